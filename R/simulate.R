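#' Configuration of the orthogonal-component mixture simulator
#'
#' Describes the validation model: `n_true_components` orthogonal
#' (disjoint-support) source components over `K` features are mixed into
#' disease samples with weights `sin^2(theta)` and into control samples with
#' weights `cos^2(theta)`, where each mixing angle theta (degrees) is drawn
#' uniformly from a sector determined by the component's role. By convention
#' component 1 is disease-specific, the last component is control-specific and
#' all others are neutral (not differentially expressed).
#'
#' Defaults are the validation-study conditions: 10 components, K = 15000
#' features, 100 disease + 100 control samples, sectors
#' [50, 89.99] / [25, 65] / [0.01, 40] degrees for disease / neutral / control
#' roles. Component amplitudes on the support are Uniform[0.5, 1.5], keeping
#' all features positive and of comparable scale.
#'
#' @param n_true_components number of ground-truth components (>= 3).
#' @param K number of features.
#' @param n_disease,n_control samples per class.
#' @param sector_disease,sector_neutral,sector_control angle intervals in
#'   degrees, each inside (0, 90).
#' @param amplitude_low,amplitude_high bounds of the uniform amplitude law on
#'   each component's support.
#' @param shuffle_support if `TRUE`, supports are a random disjoint partition
#'   instead of contiguous blocks.
#' @param seed optional integer seed used by [simulate_mixture()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_true_components = 10L, K = 15000L,
                       n_disease = 100L, n_control = 100L,
                       sector_disease = c(50, 89.99),
                       sector_neutral = c(25, 65),
                       sector_control = c(0.01, 40),
                       amplitude_low = 0.5, amplitude_high = 1.5,
                       shuffle_support = FALSE, seed = NULL) {
  n_true_components <- as.integer(n_true_components)
  K <- as.integer(K)
  if (n_true_components < 3L)
    stop("sim_config: need at least 3 components (disease, control, >=1 neutral)")
  if (n_true_components > K)
    stop("sim_config: more components (", n_true_components,
         ") than features (", K, ")")
  if (n_disease < 1L || n_control < 1L)
    stop("sim_config: need at least one sample per class")
  check_sector <- function(s, nm) {
    if (length(s) != 2L || s[1L] > s[2L] || s[1L] <= 0 || s[2L] >= 90)
      stop("sim_config: ", nm, " must be an interval inside (0, 90) degrees")
  }
  check_sector(sector_disease, "sector_disease")
  check_sector(sector_neutral, "sector_neutral")
  check_sector(sector_control, "sector_control")
  if (amplitude_low <= 0 || amplitude_high < amplitude_low)
    stop("sim_config: need 0 < amplitude_low <= amplitude_high")
  structure(list(n_true_components = n_true_components, K = K,
                 n_disease = as.integer(n_disease),
                 n_control = as.integer(n_control),
                 sector_disease = as.numeric(sector_disease),
                 sector_neutral = as.numeric(sector_neutral),
                 sector_control = as.numeric(sector_control),
                 amplitude_low = amplitude_low,
                 amplitude_high = amplitude_high,
                 shuffle_support = isTRUE(shuffle_support),
                 seed = seed),
            class = "sim_config")
}

#' Partition K features into n blocks as evenly as possible
#'
#' The first `K %% n` blocks receive one extra feature.
#' @param K,n integers, `n <= K`.
#' @return Integer vector of block sizes summing to `K`.
#' @keywords internal
even_partition <- function(K, n) {
  base <- K %/% n
  extra <- K %% n
  rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
}

#' Generate ground-truth orthogonal components
#'
#' Features are partitioned into disjoint supports (contiguous blocks, or a
#' random partition with `shuffle_support`); within its support each component
#' takes Uniform[amplitude_low, amplitude_high] values and is zero elsewhere,
#' so any two distinct components are exactly orthogonal.
#'
#' @param config a [sim_config()].
#' @return An object of class `ground_truth` with elements `components`
#'   (n_true x K), `roles` (character: disease / neutral / control), `support`
#'   (feature index of each component's block) and `angles` (`NULL` until
#'   [draw_mixing_angles()]).
#' @export
generate_components <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_true_components; K <- config$K
  sizes <- even_partition(K, n)
  order_idx <- if (config$shuffle_support) sample.int(K) else seq_len(K)
  comps <- matrix(0, n, K)
  support <- integer(K)
  pos <- 0L
  for (m in seq_len(n)) {
    idx <- order_idx[(pos + 1L):(pos + sizes[m])]
    comps[m, idx] <- runif(sizes[m], config$amplitude_low, config$amplitude_high)
    support[idx] <- m
    pos <- pos + sizes[m]
  }
  roles <- c("disease", rep("neutral", n - 2L), "control")
  structure(list(components = comps, roles = roles, support = support,
                 angles = NULL),
            class = "ground_truth")
}

role_sector <- function(role, config) {
  switch(role,
         disease = config$sector_disease,
         neutral = config$sector_neutral,
         control = config$sector_control,
         stop("unknown role: ", role))
}

#' Draw per-sample, per-component mixing angles
#'
#' Each angle theta[n, m] is drawn independently, uniform over the sector of
#' component m's role, for all N = n_disease + n_control samples.
#'
#' @param truth a `ground_truth` from [generate_components()].
#' @param config the [sim_config()] used to generate it.
#' @return `truth` with the `angles` element filled (N x n_true, degrees);
#'   disease samples occupy the first `n_disease` rows.
#' @export
draw_mixing_angles <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  n_samples <- config$n_disease + config$n_control
  m <- config$n_true_components
  angles <- matrix(NA_real_, n_samples, m)
  for (j in seq_len(m)) {
    sec <- role_sector(truth$roles[j], config)
    angles[, j] <- runif(n_samples, sec[1L], sec[2L])
  }
  truth$angles <- angles
  truth
}

#' Mix ground-truth components into a labelled dataset
#'
#' Disease sample n is `sum_m sin^2(theta[n, m]) s_m`; control sample n is
#' `sum_m cos^2(theta[n, m]) s_m`. Since `sin^2 + cos^2 = 1`, each component
#' is shared between the disease- and control-rule weights at an overall
#' concentration of 100%.
#'
#' @param truth a `ground_truth` with angles drawn.
#' @param config the matching [sim_config()].
#' @return A list with `dataset` (an [expression_dataset()]; disease samples
#'   first, labels 1 then -1) and `truth`.
#' @export
synthesize_dataset <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$angles))
  nd <- config$n_disease; nc <- config$n_control
  theta <- truth$angles * pi / 180
  weights <- rbind(sin(theta[seq_len(nd), , drop = FALSE])^2,
                   cos(theta[nd + seq_len(nc), , drop = FALSE])^2)
  values <- weights %*% truth$components
  labels <- c(rep(1, nd), rep(-1, nc))
  ids <- c(sprintf("D%03d", seq_len(nd)), sprintf("C%03d", seq_len(nc)))
  ds <- expression_dataset(values, labels,
                           feature_ids = sprintf("f%05d", seq_len(config$K)),
                           sample_ids = ids)
  list(dataset = ds, truth = truth)
}

#' Simulate a complete validation dataset
#'
#' Convenience wrapper: seeds the RNG (if `config$seed` is set), generates the
#' ground-truth components, draws the mixing angles and synthesizes the
#' labelled dataset.
#'
#' @param config a [sim_config()].
#' @return A list with `dataset` and `truth` (see [synthesize_dataset()]).
#' @export
simulate_mixture <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- generate_components(config)
  truth <- draw_mixing_angles(truth, config)
  synthesize_dataset(truth, config)
}
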