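# Shared helpers: tiny libraries and on-the-fly file fixtures.

make_small_lib <- function() {
  compound_library(
    compound_id = c("A1", "A2", "A3", "A4"),
    name = c("ethanol", "propanol", "benzene", "no structure"),
    smiles = c("CCO", "CCCO", "c1ccccc1", NA)
  )
}

# Printed reference values from the alkyl-paraben worked example: the
# standardised property vectors and the fingerprint Tanimoto coefficients
# used throughout the similarity tests.
paraben_expected <- function() {
  list(
    euclidean_distance = c("CMS-216" = 0.21, "CMS-2412" = 0.17, "CMS-2413" = 0.35),
    euclidean_similarity = c("CMS-216" = 0.82, "CMS-2412" = 0.86, "CMS-2413" = 0.74),
    pearson_similarity = c("CMS-216" = 0.99, "CMS-2412" = 0.99, "CMS-2413" = 0.93),
    aq_pearson = c("CMS-216" = 0.95, "CMS-2412" = 0.90, "CMS-2413" = 0.81),
    aq_euclidean = c("CMS-216" = 0.89, "CMS-2412" = 0.86, "CMS-2413" = 0.75)
  )
}

paraben_profile <- function() {
  p <- generate_fixture_library("parabens")
  pairwise_profile(p$library, p$target,
                   tanimoto_values = p$tanimoto[, c("toxprint", "rdkit")],
                   zscores = p$zscores)
}

# Write a 4-record SDF (3 valid + 1 deliberately corrupt) and return the path.
write_mixed_sdf <- function(path) {
  sdf <- ChemmineR::smiles2sdf(c(S1 = "CCO", S2 = "CCCO", S3 = "c1ccccc1"))
  ChemmineR::write.SDF(sdf, path)
  corrupt <- c("S4-corrupt", "", "",
               " not a counts line", "garbage atom block", "M  END", "$$$$")
  cat(paste(corrupt, collapse = "\n"), "\n", sep = "", file = path, append = TRUE)
  path
}

random_mass <- function() {
  m <- stats::runif(3)
  m <- m / sum(m)
  mass_function(m[1], m[2], m[3])
}
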