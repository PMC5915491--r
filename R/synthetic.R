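#' Specification of a synthetic block-structured dataset
#'
#' Describes a self-contained dataset with the statistical structure the
#' predictor assumes: functionally coherent miRNA blocks, phenotypically
#' coherent disease blocks, family assignments nested inside miRNA blocks,
#' and a binary association matrix whose 1-entries concentrate on matched
#' (miRNA-block, disease-block) pairings. The defaults are the
#' strong-signal study condition used throughout the package's evaluation:
#' 60 miRNAs and 30 diseases in 3 aligned blocks, within-block similarity
#' 0.7 versus 0.1 between blocks, association density 0.5 on matched block
#' pairs with 0.02 background noise.
#'
#' @param n_mirna,n_disease Entity counts.
#' @param n_mirna_blocks,n_disease_blocks Community counts; miRNA block k is
#'   associated with disease block `((k - 1) %% n_disease_blocks) + 1`.
#' @param within_sim,between_sim Mean similarity inside / between blocks, in
#'   (0, 1); `within_sim > between_sim` gives a signal fixture, equality a
#'   null fixture.
#' @param family_frac Fraction of miRNAs given a family, families being
#'   random subsets of size 2-4 inside a single miRNA block.
#' @param assoc_density Probability of a known association on matched block
#'   pairs.
#' @param noise_density Probability of a (spurious) association elsewhere.
#' @param rng_seed Integer seed; one global seed drives a fixed per-component
#'   scheme (offsets 0-3 for the miRNA similarities, disease similarities,
#'   families and associations), so components are individually reproducible.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_mirna = 60L, n_disease = 30L,
                           n_mirna_blocks = 3L, n_disease_blocks = 3L,
                           within_sim = 0.7, between_sim = 0.1,
                           family_frac = 0.5,
                           assoc_density = 0.5, noise_density = 0.02,
                           rng_seed = 1L) {
  spec <- list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
               n_mirna_blocks = as.integer(n_mirna_blocks),
               n_disease_blocks = as.integer(n_disease_blocks),
               within_sim = within_sim, between_sim = between_sim,
               family_frac = family_frac, assoc_density = assoc_density,
               noise_density = noise_density, rng_seed = as.integer(rng_seed))
  if (spec$n_mirna_blocks > spec$n_mirna ||
      spec$n_disease_blocks > spec$n_disease)
    stop("more blocks than entities", call. = FALSE)
  for (f in c("within_sim", "between_sim"))
    if (spec[[f]] <= 0 || spec[[f]] >= 1)
      stop("'", f, "' must lie in (0, 1)", call. = FALSE)
  for (f in c("family_frac", "assoc_density", "noise_density"))
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop("'", f, "' must lie in [0, 1]", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

# similarity noise is uniform on [mean - 0.05, mean + 0.05], truncated to
# [0, 1]: simple, bounded, reproducible
.sim_block_matrix <- function(n, n_blocks, within, between, labels) {
  block <- cut(seq_len(n), n_blocks, labels = FALSE)
  mean_mat <- ifelse(outer(block, block, "=="), within, between)
  # draw the upper triangle and mirror it, so every off-diagonal entry is
  # exactly uniform on [mean - 0.05, mean + 0.05] and the matrix symmetric
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- stats::runif(sum(up), -0.05, 0.05)
  noise <- noise + t(noise)
  m <- pmin(pmax(mean_mat + noise, 0), 1)
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  attr(m, "block") <- block
  m
}

#' Generate a synthetic dataset
#'
#' Draws the four inputs the predictor consumes — miRNA similarity, disease
#' similarity, family table and binary association matrix — from a
#' [synthetic_spec()]. Fully deterministic given `rng_seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `sm`, `sd` (symmetric labeled similarity matrices with
#'   unit diagonal), `family` (named character vector), `a` (binary
#'   association matrix), `mirna_block`, `disease_block` (block memberships)
#'   and the `spec` itself.
#' @export
synthetic_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  seed_of <- function(offset) (spec$rng_seed + offset) %% .Machine$integer.max

  m_labels <- sprintf("mir-%03d", seq_len(spec$n_mirna))
  d_labels <- sprintf("disease-%03d", seq_len(spec$n_disease))

  set.seed(seed_of(0L))
  sm <- .sim_block_matrix(spec$n_mirna, spec$n_mirna_blocks,
                          spec$within_sim, spec$between_sim, m_labels)
  set.seed(seed_of(1L))
  sd <- .sim_block_matrix(spec$n_disease, spec$n_disease_blocks,
                          spec$within_sim, spec$between_sim, d_labels)
  m_block <- attr(sm, "block"); attr(sm, "block") <- NULL
  d_block <- attr(sd, "block"); attr(sd, "block") <- NULL

  set.seed(seed_of(2L))
  family <- character(0L)
  target <- round(spec$family_frac * spec$n_mirna)
  unassigned <- split(seq_len(spec$n_mirna), m_block)
  fam_id <- 0L
  while (sum(lengths(unassigned) * (lengths(unassigned) >= 2L)) > 0 &&
         length(family) < target) {
    eligible <- which(lengths(unassigned) >= 2L)
    b <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    size <- min(sample(2:4, 1L), length(unassigned[[b]]),
                max(2L, target - length(family)))
    members <- if (length(unassigned[[b]]) == size) unassigned[[b]] else
      sample(unassigned[[b]], size)
    fam_id <- fam_id + 1L
    family <- c(family, stats::setNames(rep(sprintf("fam-%02d", fam_id), size),
                                        m_labels[members]))
    unassigned[[b]] <- setdiff(unassigned[[b]], members)
  }

  set.seed(seed_of(3L))
  matched_d_block <- ((m_block - 1L) %% spec$n_disease_blocks) + 1L
  p <- ifelse(outer(matched_d_block, d_block, "=="),
              spec$assoc_density, spec$noise_density)
  a <- matrix(as.integer(stats::runif(length(p)) < p),
              spec$n_mirna, spec$n_disease,
              dimnames = list(m_labels, d_labels))

  list(sm = sm, sd = sd, family = family, a = a,
       mirna_block = m_block, disease_block = d_block, spec = spec)
}

#' Randomly hold out a fraction of known associations
#'
#' Removes `ceiling(fraction * n_pairs)` known pairs uniformly at random,
#' returning the reduced training matrix and the held-out pairs; the two
#' parts are disjoint and jointly exhaustive of the known pairs.
#'
#' @param a Binary association matrix.
#' @param fraction Fraction of known pairs to hold out, in `[0, 1]`.
#' @param rng_seed Integer seed for the draw.
#' @return List with `train` (matrix) and `held_out` (data frame with
#'   `mirna_id`, `disease_id`).
#' @export
mask_associations <- function(a, fraction, rng_seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  pairs <- which(a == 1)
  k <- ceiling(fraction * length(pairs))
  set.seed(rng_seed %% .Machine$integer.max)
  sel <- if (k > 0L) pairs[sample(seq_along(pairs), k)] else integer(0L)
  train <- a
  train[sel] <- 0L
  idx <- arrayInd(sel, dim(a))
  list(train = train,
       held_out = data.frame(mirna_id = rownames(a)[idx[, 1L]],
                             disease_id = colnames(a)[idx[, 2L]],
                             stringsAsFactors = FALSE))
}
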