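#' Simulate a Yule (pure-birth) tree
#'
#' Builds an ultrametric tree by successive random coalescence of `n_tips`
#' lineages: with `k` lineages extant, the waiting time to the next join is
#' exponential with rate `k * rate`, so the expected root height is
#' `sum_{k=2}^{n} 1 / (k * rate)`.  Tips are labeled `t1..tn`.  The
#' generator is a pure function of `(n_tips, rate, seed)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (mandatory).
#' @param rate birth rate (default 1).
#' @return an ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, seed, rate = 1) {
  if (n_tips < 2L) stop("n_tips must be at least 2")
  if (missing(seed)) stop("a seed is required")
  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)

  frag <- paste0("t", seq_len(n_tips))
  height <- numeric(n_tips)
  h <- 0
  k <- n_tips
  while (k > 1L) {
    h <- h + rexp(1L, rate = rate * k)
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    frag[i] <- sprintf("(%s:%.10g,%s:%.10g)",
                       frag[i], h - height[i], frag[j], h - height[j])
    height[i] <- h
    frag <- frag[-j]; height <- height[-j]
    k <- k - 1L
  }
  parse_newick(paste0(frag[1L], ";"))
}

#' Simulate a continuous trait on a tree
#'
#' Draws one realization of trait evolution: multivariate normal with mean
#' `root` and covariance `sigma2 * V(d)`, where `V` is the tree covariance
#' and `d` the OU transform parameter (`d = 1` is pure Brownian motion,
#' `d -> 0` the star limit with independent tips).
#'
#' @param phy a `"phylo"` with branch lengths (or a `"phylo_vcv"`).
#' @param seed integer seed (mandatory).
#' @param sigma2 Brownian rate (trait units^2 per branch-length unit).
#' @param root root (ancestral mean) value.
#' @param d OU transform parameter (default 1 = Brownian).
#' @return named numeric vector of tip values.
#' @export
simulate_trait <- function(phy, seed, sigma2 = 1, root = 0, d = 1) {
  if (missing(seed)) stop("a seed is required")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  V <- .as_vcv(phy)
  if (d != 1) V <- ou_transform(V, d)
  tips <- attr(V, "tip_order")
  if (sigma2 == 0) return(setNames(rep(root, length(tips)), tips))
  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  R <- .chol_vcv(sigma2 * unclass(V))  # upper triangular, V = R'R
  setNames(root + as.numeric(crossprod(R, rnorm(length(tips)))), tips)
}

#' Simulate a full study data set
#'
#' Emulates the causal structure of a body-size / clutch-size / climate
#' comparative study: standardized climate scores `CC1` (inert) and `CC2`
#' drawn independently per species; body size responds to the
#' precipitation-like component (`SVL = svl_intercept + beta_cc2 * CC2 +`
#' Brownian noise) and clutch size responds to body size
#' (`clutch = clutch_intercept + beta_svl * SVL +` Brownian noise).
#' Defaults put the effect sizes at the magnitudes the design targets
#' (`beta_svl = 0.065` eggs/mm, `beta_cc2 = 9.8` mm/score unit) and the
#' noise scales at values producing realistic spans (SVL roughly 45-150 mm,
#' clutch roughly 1-16 eggs on a unit-height tree).
#'
#' @param phy a `"phylo"` with branch lengths.
#' @param seed integer seed (mandatory).
#' @param beta_svl effect of SVL (mm) on clutch size (eggs/mm).
#' @param beta_cc2 effect of CC2 on SVL (mm per score unit).
#' @param svl_intercept,clutch_intercept trait intercepts (mm; eggs).
#' @param svl_sigma2 Brownian rate of the SVL residual (mm^2 per unit
#'   branch length).
#' @param clutch_sigma2 Brownian rate of the clutch residual (eggs^2 per
#'   unit branch length).
#' @return a `data.frame` (class `"trait_table"`) with columns
#'   `species, SVL, clutch, CC1, CC2`; the seed is recorded as
#'   `attr(, "seed")`.
#' @export
simulate_study <- function(phy, seed, beta_svl = 0.065, beta_cc2 = 9.8,
                           svl_intercept = 90, clutch_intercept = 0.5,
                           svl_sigma2 = 400, clutch_sigma2 = 2.25) {
  if (missing(seed)) stop("a seed is required")
  V <- .as_vcv(phy)
  tips <- attr(V, "tip_order")
  n <- length(tips)
  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  cc1 <- as.numeric(scale(rnorm(n)))
  cc2 <- as.numeric(scale(rnorm(n)))
  R <- .chol_vcv(unclass(V))
  bm <- function(s2) as.numeric(crossprod(R, rnorm(n))) * sqrt(s2)
  svl <- svl_intercept + beta_cc2 * cc2 + bm(svl_sigma2)
  clutch <- clutch_intercept + beta_svl * svl + bm(clutch_sigma2)
  out <- data.frame(species = tips, SVL = svl, clutch = clutch,
                    CC1 = cc1, CC2 = cc2)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate a structured climate matrix
#'
#' Generates locality rows with the two-factor covariance structure the
#' analysis assumes: one latent temperature factor driving the six
#' temperature summaries and one latent precipitation factor driving the
#' two precipitation summaries, plus independent measurement noise.
#' Offsets keep the within-row orderings (`AMinT <= AMT <= AMaxT` etc.)
#' and positive precipitation.
#'
#' @param n_localities number of rows (localities/species).
#' @param seed integer seed (mandatory).
#' @param noise_sd measurement noise as a fraction of each variable's
#'   signal scale (default 0.1).
#' @return list with `M` (the climate matrix with columns
#'   `AP, AMT, AMinT, AMaxT, MT, MMinT, MMaxT, MP`), and the latent
#'   `temperature` and `precipitation` factors.
#' @export
simulate_climate_matrix <- function(n_localities, seed, noise_sd = 0.1) {
  if (missing(seed)) stop("a seed is required")
  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  n <- n_localities
  f_t <- rnorm(n)  # temperature factor
  f_p <- rnorm(n)  # precipitation factor
  eps <- function(scale) rnorm(n, sd = noise_sd * scale)
  amt <- 22 + 3 * f_t + eps(3)
  mt <- 24 + 3 * f_t + eps(3)
  M <- cbind(
    AP = pmax(0, 1200 + 400 * f_p + eps(400)),
    AMT = amt,
    AMinT = amt - 6 + eps(1),
    AMaxT = amt + 7 + eps(1),
    MT = mt,
    MMinT = mt - 5 + eps(1),
    MMaxT = mt + 6 + eps(1),
    MP = pmax(0, 110 + 35 * f_p + eps(35))
  )
  rownames(M) <- paste0("loc", seq_len(n))
  list(M = M, temperature = f_t, precipitation = f_p)
}

#' Packaged 21-species Tropidurinae-like fixture
#'
#' A deterministic stand-in for the study system: a 21-tip topology with
#' genus-level structure (Uranoscodon, Plica, Uracentron, Eurolophosaurus,
#' Tropidurus) and a trait table.  The topology and all trait values other
#' than four published anchors (clutch spanning 1-16 eggs with
#' *Uranoscodon superciliosus* at 16; SVL spanning 44.7-151.0 mm with
#' *Eurolophosaurus nanuzae* at 44.7 and *Plica plica* at 151.0) are
#' SYNTHETIC illustrative values, not the study's data.  Branch lengths are
#' deliberately absent, mirroring a published cladogram; assign them with
#' [assign_branch_lengths()].
#'
#' @return list with `tree` (topology-only `"phylo"`) and `traits` (a
#'   `"trait_table"` data frame: `species, SVL, clutch, CC1, CC2`).
#' @export
fixture_tropidurinae <- function() {
  nwk <- paste0(
    "((Uranoscodon_superciliosus,((Plica_plica,Plica_umbra),",
    "(Uracentron_flaviceps,Uracentron_azureum))),",
    "((Eurolophosaurus_nanuzae,Eurolophosaurus_divaricatus),",
    "(((Tropidurus_semitaeniatus,Tropidurus_mucujensis),",
    "(Tropidurus_erythrocephalus,Tropidurus_hygomi)),",
    "((Tropidurus_spinulosus,Tropidurus_guarani),",
    "((Tropidurus_etheridgei,Tropidurus_montanus),",
    "((Tropidurus_itambere,Tropidurus_oreadicus),",
    "(Tropidurus_torquatus,(Tropidurus_insulanus,",
    "(Tropidurus_hispidus,Tropidurus_cocorobensis)))))))));"
  )
  tree <- parse_newick(nwk)
  traits <- data.frame(
    species = c("Uranoscodon_superciliosus", "Plica_plica", "Plica_umbra",
                "Uracentron_flaviceps", "Uracentron_azureum",
                "Eurolophosaurus_nanuzae", "Eurolophosaurus_divaricatus",
                "Tropidurus_semitaeniatus", "Tropidurus_mucujensis",
                "Tropidurus_erythrocephalus", "Tropidurus_hygomi",
                "Tropidurus_spinulosus", "Tropidurus_guarani",
                "Tropidurus_etheridgei", "Tropidurus_montanus",
                "Tropidurus_itambere", "Tropidurus_oreadicus",
                "Tropidurus_torquatus", "Tropidurus_insulanus",
                "Tropidurus_hispidus", "Tropidurus_cocorobensis"),
    SVL = c(130.0, 151.0, 110.0, 95.0, 88.0, 44.7, 52.0, 72.0, 68.0, 75.0,
            60.0, 105.0, 80.0, 82.0, 70.0, 78.0, 85.0, 84.0, 90.0, 100.0,
            58.0),
    clutch = c(16, 1, 1, 2, 2, 1, 2, 1, 2, 2, 2, 5, 1, 3, 1, 1, 1, 1, 4,
               6, 2),
    CC1 = c(1.6, 1.2, 1.0, 0.8, 0.9, -1.1, -0.9, -0.2, -0.4, -0.6, -0.3,
            0.2, 0.1, -0.1, -1.3, -0.8, 0.4, 0.3, 0.6, 0.7, -0.5),
    CC2 = c(1.9, 1.5, 1.1, 0.9, 0.7, -1.2, -1.0, -1.4, -0.9, -0.3, -0.8,
            0.4, 0.0, -0.2, -0.6, -0.1, 0.2, 0.3, 0.5, 0.8, -0.7)
  )
  traits$CC1 <- as.numeric(scale(traits$CC1))
  traits$CC2 <- as.numeric(scale(traits$CC2))
  class(traits) <- c("trait_table", "data.frame")
  list(tree = tree, traits = traits)
}

#' Trait-table CSV I/O
#'
#' The on-disk format is a plain CSV with header
#' `species,<trait1>,<trait2>,...`; species strings are matched exactly
#' (case-sensitive) to tip labels.
#'
#' @param traits a `"trait_table"` data frame (first column `species`).
#' @param path file path.
#' @return the table, invisibly (writer) or as a `"trait_table"` (reader).
#' @export
write_trait_csv <- function(traits, path) {
  stopifnot(names(traits)[1L] == "species")
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(traits)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "species")
    stop("trait CSV must have 'species' as its first column")
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup)) stop("duplicate species in trait table: ",
                        paste(dup, collapse = ", "))
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Extract one named trait as a tip-named vector
#'
#' @param traits a `"trait_table"`.
#' @param trait column name.
#' @return named numeric vector keyed by species.
#' @export
trait_vector <- function(traits, trait) {
  if (!trait %in% names(traits)) stop("no such trait column: ", trait)
  setNames(traits[[trait]], traits$species)
}
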