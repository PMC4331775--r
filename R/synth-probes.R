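#' Construct a probe-level data container
#'
#' Probe-level intensities are stored as a positive linear-scale matrix
#' (probes x samples) plus a probeset assignment per probe row.
#'
#' @param intensity numeric matrix, probes x samples, strictly positive.
#' @param probeset character vector, length `nrow(intensity)`, mapping each
#'   probe row to its probeset (gene).
#' @return A `probe_data` list.
#' @export
probe_data <- function(intensity, probeset) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop_input("intensity must be a numeric matrix")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop_input("probe intensities must be finite and strictly positive")
  probeset <- as.character(probeset)
  if (length(probeset) != nrow(intensity))
    stop_input("probeset must have one entry per probe row")
  if (any(table(probeset) < 1L)) stop_input("empty probeset")
  structure(list(intensity = intensity, probeset = probeset),
            class = "probe_data")
}

#' Generate probe-level intensities from a log2 expression matrix
#'
#' Each probeset gets `probes_per_set` probes with fixed per-probe affinity
#' offsets (log2-normal multiplicative biases, shared across samples). The
#' observed intensity is the exponential-scale signal `2^(expr + affinity)`
#' plus an additive normal optical background — the signal+background
#' convolution the RMA background-correction step models.
#'
#' @param expr genes x samples log2 expression matrix with rownames.
#' @param cfg a [synth_config()]; uses `probes_per_set`,
#'   `probe_affinity_sd`, `bg_mean`, `bg_sd`, `seed`.
#' @return list with `data` (a [probe_data()]) and `affinity` (the
#'   probes x 1-per-gene affinity offsets, for round-trip checks).
#' @export
generate_probe_level <- function(expr, cfg = synth_config()) {
  stopifnot(is.matrix(expr), inherits(cfg, "synth_config"))
  if (any(!is.finite(expr))) stop_input("expr must be finite")
  npp <- cfg$probes_per_set
  if (npp < 1L) stop_input("probes_per_set must be >= 1")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("gene_%05d", seq_len(nrow(expr)))
  with_seed(cfg$seed + SEED_OFFSET_PROBES, {
    n_probe <- npp * nrow(expr)
    affinity <- stats::rnorm(n_probe, 0, cfg$probe_affinity_sd)
    probeset <- rep(genes, each = npp)
    probe_id <- sprintf("%s_at%02d", probeset, rep(seq_len(npp), nrow(expr)))
    signal <- 2 ^ (expr[probeset, , drop = FALSE] + affinity)
    bg <- if (cfg$bg_mean == 0 && cfg$bg_sd == 0) 0 else
      matrix(stats::rnorm(n_probe * ncol(expr), cfg$bg_mean, cfg$bg_sd),
             n_probe, ncol(expr))
    intensity <- pmax(signal + bg, 1e-6)
    dimnames(intensity) <- list(probe_id, colnames(expr))
    list(data = probe_data(intensity, probeset), affinity = affinity)
  })
}
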