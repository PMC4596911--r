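#' Construct a pedigree
#'
#' Builds a validated pedigree object from per-individual records. Families
#' (`fid`) partition the sample; individuals in different families are treated
#' as unrelated. Founders have both parent ids missing (`NA` or `"0"`).
#'
#' @param fid character vector of family ids.
#' @param iid character vector of individual ids, unique within the sample.
#' @param father,mother character vectors of parent ids (`NA` or `"0"` for
#'   founders). A referenced father must be male and a referenced mother
#'   female, and both must belong to the same family as the child.
#' @param sex `"male"`/`"female"` (or PLINK codes 1/2); `NA` allowed for
#'   autosomal-only analyses.
#' @param affection case-control status (1 = affected, 0 = unaffected,
#'   `NA` = missing) or a quantitative phenotype value.
#'
#' @return An object of class `"fam_pedigree"`: a data frame with columns
#'   `fid`, `iid`, `father`, `mother`, `sex`, `affection` plus integer parent
#'   indices (`fidx`, `midx`, 0 = founder) and generation `depth`.
#' @examples
#' ped <- pedigree(fid = c("F1", "F1", "F1"),
#'                 iid = c("dad", "mom", "kid"),
#'                 father = c(NA, NA, "dad"),
#'                 mother = c(NA, NA, "mom"),
#'                 sex = c("male", "female", "female"),
#'                 affection = c(0, 0, 1))
#' @export
pedigree <- function(fid, iid, father = NA, mother = NA, sex = NA,
                     affection = NA) {
  n <- length(iid)
  fid <- rep_len(as.character(fid), n)
  iid <- as.character(iid)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  father[father %in% c("0", "")] <- NA_character_
  mother[mother %in% c("0", "")] <- NA_character_
  sex <- .parse_sex(rep_len(sex, n))
  affection <- rep_len(as.numeric(affection), n)

  if (anyDuplicated(iid))
    stop("duplicated individual ids: ",
         paste(unique(iid[duplicated(iid)]), collapse = ", "))

  fidx <- match(father, iid)
  midx <- match(mother, iid)
  if (any(!is.na(father) & is.na(fidx)))
    stop("unknown father id(s): ",
         paste(unique(father[!is.na(father) & is.na(fidx)]), collapse = ", "))
  if (any(!is.na(mother) & is.na(midx)))
    stop("unknown mother id(s): ",
         paste(unique(mother[!is.na(mother) & is.na(midx)]), collapse = ", "))
  fidx[is.na(fidx)] <- 0L
  midx[is.na(midx)] <- 0L

  bad <- fidx > 0L & !(sex[pmax(fidx, 1L)] %in% "male")
  if (any(bad, na.rm = TRUE))
    stop("father is not male for individual(s): ",
         paste(iid[which(bad)], collapse = ", "))
  bad <- midx > 0L & !(sex[pmax(midx, 1L)] %in% "female")
  if (any(bad, na.rm = TRUE))
    stop("mother is not female for individual(s): ",
         paste(iid[which(bad)], collapse = ", "))
  bad <- (fidx > 0L & fid[pmax(fidx, 1L)] != fid) |
         (midx > 0L & fid[pmax(midx, 1L)] != fid)
  if (any(bad))
    stop("parent in a different family for individual(s): ",
         paste(iid[which(bad)], collapse = ", "))
  if (any((fidx > 0L) != (midx > 0L)))
    stop("individuals must have either both parents or neither: ",
         paste(iid[which((fidx > 0L) != (midx > 0L))], collapse = ", "))

  depth <- .pedigree_depth(fidx, midx, iid)

  ped <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                    sex = sex, affection = affection,
                    fidx = fidx, midx = midx, depth = depth,
                    stringsAsFactors = FALSE)
  class(ped) <- c("fam_pedigree", "data.frame")
  ped
}

.parse_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  x <- tolower(as.character(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  if (any(!is.na(x) & !(x %in% c("1", "2", "m", "f", "male", "female",
                                 "0", "na", "unknown"))))
    stop("unrecognized sex code(s): ",
         paste(unique(x[!x %in% c("1", "2", "m", "f", "male", "female",
                                  "0", "na", "unknown")]), collapse = ", "))
  out
}

# Generation depth by iterative relaxation; cycles (an individual its own
# ancestor) never converge and are reported as an error.
.pedigree_depth <- function(fidx, midx, iid) {
  n <- length(fidx)
  depth <- rep(0L, n)
  for (iter in seq_len(n + 1L)) {
    pd <- pmax(ifelse(fidx > 0L, depth[pmax(fidx, 1L)], -1L),
               ifelse(midx > 0L, depth[pmax(midx, 1L)], -1L))
    new <- pd + 1L
    if (all(new == depth)) return(depth)
    depth <- new
  }
  stop("pedigree contains an ancestry cycle (an individual is its own ",
       "ancestor)")
}

#' Read a PLINK-style .fam pedigree file
#'
#' Whitespace-delimited, six columns in PLINK order: FID IID PAT MAT SEX
#' PHENO. SEX is 1 = male, 2 = female, 0 = unknown. A parent id of `"0"`
#' marks a founder.
#'
#' @param path file path.
#' @param affection_coding `"plink"` (1 = unaffected, 2 = affected, 0 or -9 =
#'   missing) or `"01"` (0 = unaffected, 1 = affected, -9/NA = missing).
#' @param quantitative if `TRUE` the phenotype column is taken as a
#'   quantitative value (-9 = missing).
#' @return A [pedigree()] object.
#' @export
read_fam <- function(path, affection_coding = c("plink", "01"),
                     quantitative = FALSE) {
  affection_coding <- match.arg(affection_coding)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "pheno"))
  ph <- suppressWarnings(as.numeric(tab$pheno))
  if (quantitative) {
    aff <- ifelse(ph == -9, NA_real_, ph)
  } else if (affection_coding == "plink") {
    aff <- rep(NA_real_, length(ph))
    aff[ph == 1] <- 0
    aff[ph == 2] <- 1
  } else {
    aff <- ifelse(is.na(ph) | ph == -9, NA_real_, ph)
    if (any(!is.na(aff) & !(aff %in% c(0, 1))))
      stop("affection values outside {0, 1} under '01' coding")
  }
  pedigree(fid = tab$fid, iid = tab$iid, father = tab$father,
           mother = tab$mother, sex = tab$sex, affection = aff)
}

#' @export
print.fam_pedigree <- function(x, ...) {
  cat(sprintf("<fam_pedigree> %d individuals in %d families (%d founders)\n",
              nrow(x), length(unique(x$fid)), sum(x$fidx == 0L)))
  NextMethod()
}

.ped_index <- function(ped, ids) {
  idx <- match(as.character(ids), ped$iid)
  if (anyNA(idx))
    stop("unknown individual id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}
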