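# Pedigree builders shared across tests.

sib_ped <- function(sexes = c("female", "female")) {
  n <- length(sexes)
  pedigree(fid = "F1",
           iid = c("f", "m", paste0("s", seq_len(n))),
           father = c(NA, NA, rep("f", n)),
           mother = c(NA, NA, rep("m", n)),
           sex = c("male", "female", sexes),
           affection = c(NA, NA, rep(0, n)))
}

first_cousins_ped <- function() {
  pedigree(fid = "F1",
           iid = c("g1", "g2", "a", "b", "wa", "wb", "i", "j"),
           father = c(NA, NA, "g1", "g1", NA, NA, "a", "b"),
           mother = c(NA, NA, "g2", "g2", NA, NA, "wa", "wb"),
           sex = c("male", "female", "male", "male", "female", "female",
                   "male", "female"))
}

double_first_cousins_ped <- function() {
  pedigree(fid = "F1",
           iid = c("g1", "g2", "g3", "g4", "a", "b", "c", "d", "i", "j"),
           father = c(NA, NA, NA, NA, "g1", "g1", "g3", "g3", "a", "b"),
           mother = c(NA, NA, NA, NA, "g2", "g2", "g4", "g4", "c", "d"),
           sex = c("male", "female", "male", "female", "male", "male",
                   "female", "female", "male", "female"))
}

# Three generations for X-linked checks: grandparents gf x gm have son "u"
# (a maternal uncle), daughters "s" and "s2"; s marries founder "h", with
# daughter "n" (niece) and son "b" (nephew).
three_gen_ped <- function() {
  pedigree(fid = "F1",
           iid = c("gf", "gm", "u", "s", "s2", "h", "n", "b"),
           father = c(NA, NA, "gf", "gf", "gf", NA, "h", "h"),
           mother = c(NA, NA, "gm", "gm", "gm", NA, "s", "s"),
           sex = c("male", "female", "male", "female", "female", "male",
                   "female", "male"))
}

# Small unrelated case-control sample as pedigree + single-marker genotypes.
unrelated_cc_data <- function(g, y, chrom = "1") {
  n <- length(g)
  ped <- pedigree(fid = sprintf("U%03d", seq_len(n)),
                  iid = sprintf("id%03d", seq_len(n)),
                  sex = rep(c("male", "female"), length.out = n),
                  affection = y)
  geno <- as_geno_matrix(matrix(g, nrow = 1,
                                dimnames = list("M1", ped$iid)),
                         markers = data.frame(marker = "M1", chrom = chrom,
                                              pos = 1L, a1 = "A", a2 = "B"))
  list(ped = ped, geno = geno)
}
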