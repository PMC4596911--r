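# Genotype readers (VCF GT/DS/GP, Oxford .gen/.sample, plain TSV dosage),
# the result writer, and the command-line front-end.

#' Construct a genotype matrix object
#'
#' The package's in-memory genotype container: markers in rows, samples in
#' columns, dosages on the additive 0..2 scale (X-linked males 0/2), with
#' optional per-marker posterior probability matrices.
#'
#' @param dosage numeric matrix (markers x samples) with dimnames; `NA` =
#'   missing.
#' @param markers data frame with columns `marker`, `chrom`, `pos`, `a1`,
#'   `a2` (one row per dosage row); an `info` column, if present, is kept as
#'   pass-through imputation-quality metadata.
#' @param post optional list (one element per marker) of n x 3 posterior
#'   matrices, or `NULL` per marker for hard calls.
#' @return A list of class `"geno_matrix"` with elements `samples`,
#'   `markers` (with an `is_x` flag derived from `chrom`), `dosage`, `post`.
#' @export
as_geno_matrix <- function(dosage, markers, post = NULL) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  if (is.null(colnames(dosage))) stop("dosage must have sample column names")
  stopifnot(nrow(markers) == nrow(dosage))
  markers$is_x <- toupper(as.character(markers$chrom)) %in%
    c("X", "23", "CHRX")
  structure(list(samples = colnames(dosage), markers = markers,
                 dosage = dosage, post = post),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d samples (%s)\n",
              nrow(x$dosage), length(x$samples),
              if (is.null(x$post)) "hard calls/dosages"
              else "with posteriors"))
  invisible(x)
}

#' Read genotypes from file
#'
#' Supported formats: VCF 4.x (GT hard calls, DS dosages, GP posterior
#' triples in 0/1/2 order), Oxford `.gen` with a `.sample` file (posterior
#' triples per marker), and a TSV dosage dialect (columns `marker chrom pos
#' a1 a2` then one dosage column per sample). GP triples whose sum deviates
#' from 1 by more than 0.01 are an error; smaller deviations are
#' renormalized. On X-linked markers, a heterozygous male hard call is set
#' missing with a warning.
#'
#' @param path genotype file.
#' @param format `"auto"` (by extension), `"vcf"`, `"gen"` or `"tsv"`.
#' @param sample_file `.sample` file accompanying a `.gen` file.
#' @param ped optional [pedigree()] used to resolve sexes for X-linked male
#'   validation.
#' @return A `geno_matrix` (see [as_geno_matrix()]).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "gen", "tsv"),
                           sample_file = NULL, ped = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.gen$", path)) "gen"
              else "tsv"
  }
  gm <- switch(format,
               vcf = .read_vcf(path),
               gen = .read_gen(path, sample_file),
               tsv = .read_tsv_dosage(path))
  if (!is.null(ped)) gm <- .validate_x_males(gm, ped)
  gm
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  markers <- data.frame(marker = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                        paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                        fix[, "ID"]),
                        chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        a1 = fix[, "REF"], a2 = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  nm <- nrow(markers)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  dsf <- tryCatch(vcfR::extract.gt(v, element = "DS"), error = function(e) NULL)
  gpf <- tryCatch(vcfR::extract.gt(v, element = "GP"), error = function(e) NULL)
  samples <- colnames(v@gt)[-1]
  ns <- length(samples)
  dosage <- matrix(NA_real_, nm, ns, dimnames = list(markers$marker, samples))

  hard <- NULL
  if (!is.null(gt)) {
    hard <- matrix(NA_real_, nm, ns)
    al <- gsub("\\|", "/", gt)
    hard[al %in% c("0/0", "0")] <- 0
    hard[al %in% c("0/1", "1/0")] <- 1
    hard[al == "1/1"] <- 2
    # hemizygous single-allele alternative calls code as 2
    hard[al == "1"] <- 2
  }

  # per-marker priority: GP posteriors > DS dosage > GT hard call
  post <- NULL
  if (!is.null(gpf)) {
    post <- vector("list", nm)
    for (i in seq_len(nm)) {
      trip <- t(vapply(gpf[i, ], function(s) {
        if (is.na(s)) return(c(NA_real_, NA_real_, NA_real_))
        as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
      }, numeric(3)))
      ok <- !is.na(trip[, 1])
      if (!any(ok)) { post[i] <- list(NULL); next }
      if (any(ok & abs(rowSums(trip) - 1) > 1e-2))
        stop("GP triples failing the sum-to-one check at marker ",
             markers$marker[i])
      trip[ok, ] <- trip[ok, , drop = FALSE] /
        rowSums(trip[ok, , drop = FALSE])
      # samples without GP fall back to a degenerate hard-call posterior
      if (any(!ok) && !is.null(hard)) {
        fb <- which(!ok & !is.na(hard[i, ]))
        if (length(fb)) trip[fb, ] <- diag(3)[hard[i, fb] + 1, ]
        ok[fb] <- TRUE
      }
      post[[i]] <- trip
      dosage[i, ok] <- trip[ok, 2] + 2 * trip[ok, 3]
    }
  }
  if (!is.null(dsf)) {
    ds <- suppressWarnings(matrix(as.numeric(dsf), nm, ns))
    use <- is.na(dosage) & !is.na(ds)
    dosage[use] <- ds[use]
  }
  if (!is.null(hard)) {
    use <- is.na(dosage) & !is.na(hard)
    dosage[use] <- hard[use]
  }
  as_geno_matrix(dosage, markers, post = post)
}

.read_gen <- function(path, sample_file) {
  if (is.null(sample_file))
    stop("a .sample file is required with Oxford .gen input")
  smp <- utils::read.table(sample_file, header = TRUE,
                           colClasses = "character")
  smp <- smp[-1, , drop = FALSE]                 # second header (type) row
  samples <- smp$ID_2
  if (is.null(samples)) samples <- smp[[2]]
  gen <- utils::read.table(path, header = FALSE)
  nm <- nrow(gen)
  n <- length(samples)
  if (ncol(gen) != 6 + 3 * n)
    stop(".gen column count does not match the .sample file")
  # Oxford .gen columns: chr snpid rsid pos a1 a2, then one triple per sample
  markers <- data.frame(marker = as.character(gen[[3]]),
                        chrom = as.character(gen[[1]]),
                        pos = as.integer(gen[[4]]),
                        a1 = as.character(gen[[5]]),
                        a2 = as.character(gen[[6]]),
                        stringsAsFactors = FALSE)
  tri <- as.matrix(gen[, -(1:6), drop = FALSE])
  post <- vector("list", nm)
  dosage <- matrix(NA_real_, nm, n, dimnames = list(markers$marker, samples))
  for (i in seq_len(nm)) {
    trip <- matrix(tri[i, ], ncol = 3, byrow = TRUE)
    s <- rowSums(trip)
    if (any(abs(s - 1) > 1e-2))
      stop("genotype probability triples failing the sum-to-one check at ",
           markers$marker[i])
    trip <- trip / s
    post[[i]] <- trip
    dosage[i, ] <- trip[, 2] + 2 * trip[, 3]
  }
  as_geno_matrix(dosage, markers, post = post)
}

.read_tsv_dosage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(tab)))
    stop("TSV dosage file must have columns ", paste(need, collapse = ", "))
  meta <- intersect(c(need, "info"), names(tab))
  samples <- setdiff(names(tab), meta)
  dosage <- as.matrix(tab[, samples, drop = FALSE])
  rownames(dosage) <- tab$marker
  as_geno_matrix(dosage, tab[, meta, drop = FALSE])
}

# On X markers, heterozygous male hard calls are impossible; set missing.
.validate_x_males <- function(gm, ped) {
  xrows <- which(gm$markers$is_x)
  if (!length(xrows)) return(gm)
  idx <- match(gm$samples, ped$iid)
  male <- !is.na(idx) & ped$sex[pmax(idx, 1L)] %in% "male"
  if (!any(male)) return(gm)
  for (i in xrows) {
    het <- male & !is.na(gm$dosage[i, ]) & gm$dosage[i, ] == 1 &
      (is.null(gm$post) || is.null(gm$post[[i]]))
    if (any(het)) {
      warning(sum(het), " heterozygous male call(s) on X marker ",
              gm$markers$marker[i], " set to missing")
      gm$dosage[i, het] <- NA_real_
    }
  }
  gm
}

#' Run score tests across all markers and write/return a results table
#'
#' @param ped a [pedigree()].
#' @param geno a `geno_matrix`.
#' @param model genetic model.
#' @param fam_history if `TRUE` use [weighted_score_test()].
#' @param freq_source `"pooled"` or `"controls"`.
#' @param min_maf,min_r2t marker filters (applied to the pooled allele
#'   frequency and to R2_T).
#' @param chromosome override per-marker chromosome metadata (`NULL` =
#'   use it).
#' @return A data frame with one row per tested marker: `marker`, `chrom`,
#'   `pos`, `al1`, `al2`, `N0`, `N1`, `EAF0`, `EAF1`, `U`, `VAR`, `CHI2`,
#'   `P`, `R2T`, `STATUS`. Filtered markers appear with `STATUS =
#'   "filtered"`.
#' @export
assoc_scan <- function(ped, geno, model = "additive", fam_history = FALSE,
                       freq_source = "pooled", min_maf = 0, min_r2t = 0,
                       chromosome = NULL) {
  rows <- vector("list", nrow(geno$markers))
  for (i in seq_len(nrow(geno$markers))) {
    mk <- geno$markers$marker[i]
    res <- if (fam_history)
      weighted_score_test(ped, geno, mk, model = model,
                          chromosome = chromosome,
                          freq_source = freq_source)
    else
      run_score_test(ped, geno, mk, model = model, chromosome = chromosome,
                     freq_source = freq_source)
    status <- res$status
    if (status == "ok") {
      maf <- if (is.na(res$p_hat)) NA_real_ else min(res$p_hat, 1 - res$p_hat)
      if (!is.na(maf) && maf < min_maf) status <- "filtered"
      if (!is.na(res$r2T) && res$r2T < min_r2t) status <- "filtered"
    }
    rows[[i]] <- data.frame(
      marker = mk, chrom = geno$markers$chrom[i], pos = geno$markers$pos[i],
      al1 = geno$markers$a1[i], al2 = geno$markers$a2[i],
      N0 = res$n_controls, N1 = res$n_cases,
      EAF0 = res$eaf_controls, EAF1 = res$eaf_cases,
      U = res$U, VAR = res$V, CHI2 = res$chi2, P = res$p, R2T = res$r2T,
      STATUS = status, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an association results table as TSV
#'
#' @param results data frame from [assoc_scan()].
#' @param path output file.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset as pedigree + genotype files
#'
#' Produces `<prefix>.fam` (PLINK dialect, affected = 2) and
#' `<prefix>.tsv` (the package's TSV dosage dialect), so simulator output
#' round-trips through [read_fam()] / [read_genotypes()].
#'
#' @param ds a [simulate_dataset()] result.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  dat <- sim_to_data(ds)
  ped <- dat$ped
  pheno <- ifelse(is.na(ped$affection), "-9",
                  ifelse(ped$affection == 1, "2", "1"))
  fam <- data.frame(ped$fid, ped$iid,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ifelse(ped$sex == "male", 1L, 2L), pheno)
  fam_path <- paste0(prefix, ".fam")
  utils::write.table(fam, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- dat$geno
  tsv <- data.frame(g$markers[, c("marker", "chrom", "pos", "a1", "a2")],
                    as.data.frame(g$dosage, check.names = FALSE))
  tsv_path <- paste0(prefix, ".tsv")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fam = fam_path, tsv = tsv_path))
}

#' Command-line front end
#'
#' Subcommands: `assoc` (score tests over a marker file), `simulate`
#' (write one ascertained dataset), `power` (empirical type-I error /
#' power). Designed to be called from the thin `inst/cli/famscore`
#' Rscript wrapper.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || !(args[1] %in% c("assoc", "simulate", "power"))) {
    message("usage: famscore <assoc|simulate|power> [options]")
    return(invisible(1L))
  }
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface requires the 'optparse' package")
  sub <- args[1]
  rest <- args[-1]
  o <- optparse::make_option
  status <- 0L
  if (sub == "assoc") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      o("--ped", type = "character"),
      o("--geno", type = "character"),
      o("--format", type = "character", default = "auto"),
      o("--sample-file", type = "character", default = NULL,
        dest = "sample_file"),
      o("--model", type = "character", default = "additive"),
      o("--chr-x", action = "store_true", default = FALSE, dest = "chr_x"),
      o("--fam-history", action = "store_true", default = FALSE,
        dest = "fam_history"),
      o("--freq-source", type = "character", default = "pooled",
        dest = "freq_source"),
      o("--min-maf", type = "double", default = 0, dest = "min_maf"),
      o("--min-r2t", type = "double", default = 0, dest = "min_r2t"),
      o("--out", type = "character", default = "famscore_results.tsv"),
      o("--seed", type = "integer", default = NULL))), args = rest)
    if (is.null(opts$ped) || is.null(opts$geno))
      stop("assoc requires --ped and --geno")
    if (!is.null(opts$seed)) set.seed(opts$seed)
    ped <- read_fam(opts$ped)
    geno <- read_genotypes(opts$geno, format = opts$format,
                           sample_file = opts$sample_file, ped = ped)
    res <- assoc_scan(ped, geno, model = opts$model,
                      fam_history = opts$fam_history,
                      freq_source = opts$freq_source,
                      min_maf = opts$min_maf, min_r2t = opts$min_r2t,
                      chromosome = if (opts$chr_x) "X")
    write_results(res, opts$out)
    message(sprintf("tested %d, filtered %d, degenerate %d of %d markers",
                    sum(res$STATUS == "ok"), sum(res$STATUS == "filtered"),
                    sum(res$STATUS == "degenerate"), nrow(res)))
  } else {
    common <- list(
      o("--scheme", type = "character", default = "ASP1"),
      o("--maf", type = "double", default = 0.3),
      o("--or", type = "double", default = 1, dest = "or_"),
      o("--sigma-u2", type = "double", default = 1, dest = "sigma_u2"),
      o("--h2", type = "character", default = NULL,
        help = "shorthand: 25 => sigma_u2 = 1, 14 => sigma_u2 = 0.5"),
      o("--model", type = "character", default = "additive"),
      o("--chr-x", action = "store_true", default = FALSE, dest = "chr_x"),
      o("--n-cases", type = "integer", default = NULL, dest = "n_cases"),
      o("--n-controls", type = "integer", default = NULL,
        dest = "n_controls"),
      o("--seed", type = "integer", default = NULL))
    extra <- if (sub == "power") list(
      o("--reps", type = "integer", default = 1000),
      o("--alpha", type = "double", default = 0.05),
      o("--test", type = "character", default = "ST"),
      o("--out", type = "character", default = NULL))
    else list(o("--out-prefix", type = "character", default = "famscore_sim",
                dest = "out_prefix"))
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = c(common, extra)), args = rest)
    if (!is.null(opts$h2))
      opts$sigma_u2 <- switch(opts$h2, "25" = 1, "14" = 0.5,
                              stop("--h2 must be 25 or 14"))
    if (!is.null(opts$seed)) set.seed(opts$seed)
    cfg <- sim_config(maf = opts$maf, odds_ratio = opts$or_,
                      sigma_u2 = opts$sigma_u2, scheme = opts$scheme,
                      disease_model = opts$model,
                      chromosome = if (opts$chr_x) "X" else "autosome",
                      n_case_families = opts$n_cases,
                      n_controls = opts$n_controls,
                      replicates = if (sub == "power") opts$reps else 1L,
                      alpha = if (sub == "power") opts$alpha else 0.05)
    if (sub == "simulate") {
      ds <- simulate_dataset(cfg)
      paths <- write_dataset(ds, opts$out_prefix)
      message("wrote ", paste(paths, collapse = " and "))
    } else {
      res <- empirical_rate(cfg, test = opts$test)
      tab <- data.frame(scheme = cfg$scheme, model = cfg$disease_model,
                        chromosome = cfg$chromosome, maf = cfg$maf,
                        or_ = cfg$odds_ratio, sigma_u2 = cfg$sigma_u2,
                        test = opts$test, reps = cfg$replicates,
                        rate = res$rate, se = res$se,
                        degenerate = res$n_degenerate)
      names(tab)[names(tab) == "or_"] <- "or"
      if (!is.null(opts$out)) {
        utils::write.table(tab, opts$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else {
        utils::write.table(tab, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
  }
  invisible(status)
}
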