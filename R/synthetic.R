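#' Specification for a two-modality synthetic dataset
#'
#' Describes a generative model for unpaired two-modality data with known
#' ground truth: cells of `n_types` types (imbalanced via `proportions`)
#' occupy a shared latent state space; each modality observes the latent
#' states through its own loading matrix, with `p_link` linked feature
#' pairs whose loading vectors are shared across modalities to a tunable
#' degree (`linkage_strength`, the expected cross-modality correlation of
#' a linked pair on truly paired cells), plus modality-specific features
#' and isotropic observation noise.
#'
#' @param n_types number of cell types.
#' @param proportions type proportions, summing to 1.
#' @param nx,ny cell counts, `nx <= ny`; the first `nx` y-cells share
#'   latent states (true pairing) with the x-cells.
#' @param latent_dim latent state dimension.
#' @param px,py feature counts; `p_link <= min(px, py)`.
#' @param p_link number of linked feature pairs (shared names).
#' @param linkage_strength in `[0, 1]`: 1 = identical linked loadings,
#'   0 = independent.
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types, proportions, nx, ny, latent_dim = 10,
                           px, py, p_link, linkage_strength, noise_sd,
                           seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_mmihcl("proportions must sum to 1")
  if (length(proportions) != n_types)
    stop_mmihcl("need one proportion per type")
  if (nx > ny) stop_mmihcl("nx must be <= ny")
  if (p_link > min(px, py)) stop_mmihcl("p_link must be <= min(px, py)")
  if (linkage_strength < 0 || linkage_strength > 1)
    stop_mmihcl("linkage_strength must be in [0, 1]")
  if (noise_sd < 0) stop_mmihcl("noise_sd must be >= 0")
  structure(list(n_types = as.integer(n_types), proportions = proportions,
                 nx = as.integer(nx), ny = as.integer(ny),
                 latent_dim = as.integer(latent_dim),
                 px = as.integer(px), py = as.integer(py),
                 p_link = as.integer(p_link),
                 linkage_strength = linkage_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a two-modality synthetic dataset with ground truth
#'
#' Type means are drawn once (sd 2 around the origin in latent space);
#' each cell's latent state is its type mean plus unit isotropic noise.
#' Modality matrices are `Z %*% A + noise`: linked columns of the two
#' loading matrices satisfy `a_y = s * a_x + sqrt(1 - s^2) * b` with
#' independent `b` (so `s = linkage_strength` is the expected cross-modal
#' loading correlation), unlinked columns are independent; loading entries
#' have variance `1/latent_dim`. The first `nx` y-cells reuse the x latent
#' states and labels, giving a known true pairing. Linked features carry
#' identical names in both modalities so that [link_by_name()] recovers
#' the linkage.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `mmihcl_sim`: `x`, `y` ([modality_matrix()]s with
#'   labels), `linkage` (a [feature_linkage()]), `true_pairs` (two-column
#'   matrix pairing x-cells with their latent twins in y), `spec`.
#' @export
generate_multimodal <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ld <- spec$latent_dim
    means <- matrix(rnorm(spec$n_types * ld, sd = 2), spec$n_types, ld)
    lab_x <- sample.int(spec$n_types, spec$nx, replace = TRUE,
                        prob = spec$proportions)
    z_x <- means[lab_x, , drop = FALSE] +
      matrix(rnorm(spec$nx * ld), spec$nx, ld)
    n_extra <- spec$ny - spec$nx
    lab_extra <- if (n_extra > 0)
      sample.int(spec$n_types, n_extra, replace = TRUE, prob = spec$proportions)
    z_extra <- if (n_extra > 0)
      means[lab_extra, , drop = FALSE] + matrix(rnorm(n_extra * ld), n_extra, ld)
    lab_y <- c(lab_x, lab_extra)
    z_y <- rbind(z_x, z_extra)

    lsd <- 1 / sqrt(ld)
    a_link_x <- matrix(rnorm(ld * spec$p_link, sd = lsd), ld, spec$p_link)
    b_link <- matrix(rnorm(ld * spec$p_link, sd = lsd), ld, spec$p_link)
    s <- spec$linkage_strength
    a_link_y <- s * a_link_x + sqrt(1 - s^2) * b_link
    a_x <- cbind(a_link_x,
                 matrix(rnorm(ld * (spec$px - spec$p_link), sd = lsd),
                        ld, spec$px - spec$p_link))
    a_y <- cbind(a_link_y,
                 matrix(rnorm(ld * (spec$py - spec$p_link), sd = lsd),
                        ld, spec$py - spec$p_link))

    xv <- z_x %*% a_x +
      matrix(rnorm(spec$nx * spec$px, sd = spec$noise_sd), spec$nx, spec$px)
    yv <- z_y %*% a_y +
      matrix(rnorm(spec$ny * spec$py, sd = spec$noise_sd), spec$ny, spec$py)

    f_link <- sprintf("LINK_%03d", seq_len(spec$p_link))
    type_names <- paste0("type", seq_len(spec$n_types))
    x <- modality_matrix(
      xv,
      feature_ids = c(f_link, sprintf("XF_%04d", seq_len(spec$px - spec$p_link))),
      cell_ids = sprintf("x_cell_%04d", seq_len(spec$nx)),
      cell_type_labels = type_names[lab_x], modality_tag = "mod_x")
    y <- modality_matrix(
      yv,
      feature_ids = c(f_link, sprintf("YF_%04d", seq_len(spec$py - spec$p_link))),
      cell_ids = sprintf("y_cell_%04d", seq_len(spec$ny)),
      cell_type_labels = type_names[lab_y], modality_tag = "mod_y")
    structure(list(x = x, y = y, linkage = link_by_name(x, y),
                   true_pairs = cbind(x = seq_len(spec$nx), y = seq_len(spec$nx)),
                   spec = spec),
              class = "mmihcl_sim")
  })
}

#' Reference synthetic fixtures
#'
#' Three named presets spanning the regimes the pipeline targets:
#' \describe{
#'   \item{`easy_strong`}{3 types (0.5/0.3/0.2), 600 + 600 cells, 200
#'     features each, 60 linked pairs (rho = 0.3, strong), linkage
#'     strength 0.9, noise 0.3.}
#'   \item{`hard_weak`}{5 types (0.45/0.30/0.15/0.07/0.03), 800 + 1000
#'     cells, 2000 vs 120 features, 40 linked pairs (rho = 0.02, weak),
#'     linkage strength 0.4, noise 0.8.}
#'   \item{`imbalanced_aknn`}{6 types spanning proportions 0.3033 down to
#'     0.0234 (a ~13-fold spread), 1200 + 1200 cells, 300 features each,
#'     80 linked pairs, linkage strength 0.9, noise 0.3.}
#' }
#'
#' @param seed seed stored in each spec (override per use).
#' @return named list of [synthetic_spec()] objects.
#' @export
reference_fixtures <- function(seed = 1L) {
  list(
    easy_strong = synthetic_spec(
      n_types = 3, proportions = c(0.5, 0.3, 0.2), nx = 600, ny = 600,
      latent_dim = 10, px = 200, py = 200, p_link = 60,
      linkage_strength = 0.9, noise_sd = 0.3, seed = seed),
    hard_weak = synthetic_spec(
      n_types = 5, proportions = c(0.45, 0.30, 0.15, 0.07, 0.03),
      nx = 800, ny = 1000, latent_dim = 10, px = 2000, py = 120, p_link = 40,
      linkage_strength = 0.4, noise_sd = 0.8, seed = seed),
    imbalanced_aknn = synthetic_spec(
      n_types = 6, proportions = c(0.3033, 0.25, 0.18, 0.15, 0.0933, 0.0234),
      nx = 1200, ny = 1200, latent_dim = 10, px = 300, py = 300, p_link = 80,
      linkage_strength = 0.9, noise_sd = 0.3, seed = seed))
}

#' Downsample a feature linkage
#'
#' Seeded uniform subsample of the linked pairs to
#' `ceiling(fraction * p_link)` pairs; the linkage ratio is recomputed.
#' Used to stress-test resilience to sparse linkage.
#'
#' @param linkage a [feature_linkage()].
#' @param fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return A [feature_linkage()].
#' @export
downsample_linkage <- function(linkage, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop_mmihcl("fraction must be in (0, 1]")
  keep_n <- ceiling(fraction * linkage$p_link)
  if (keep_n < 1) stop_mmihcl("fraction yields zero pairs")
  if (keep_n == linkage$p_link) return(linkage)
  idx <- with_seed(seed, sort(sample.int(linkage$p_link, keep_n)))
  feature_linkage(linkage$pairs[idx, , drop = FALSE], linkage$px, linkage$py,
                  x_names = linkage$x_names[idx], y_names = linkage$y_names[idx])
}
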