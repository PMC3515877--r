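# Clustered expression-profile simulator (stand-in for a tissue-series
# expression atlas): genes in a cluster share a latent per-sample profile;
# within-cluster correlation rises with within_cluster_rho.

#' Simulate a clustered expression matrix
#'
#' Gene g in cluster c gets
#' x_g = sqrt(rho) z_c + sqrt(1 - rho) noise_sd eta_g
#' with z_c and eta_g independent standard normal per sample, so
#' noise_sd = 0 (or rho = 1) makes genes within a cluster perfectly
#' correlated.
#'
#' @param n_samples Number of samples (>= 2; correlation is undefined for
#'   one sample).
#' @param cluster_map Named character/integer vector mapping every gene id
#'   to its cluster.
#' @param within_cluster_rho Shared-signal weight in [0, 1].
#' @param noise_sd Standard deviation of the private noise.
#' @param seed Optional integer seed.
#' @return Numeric matrix (genes x samples) with dimnames; attribute
#'   \code{cluster_map} records the truth.
#' @export
simulate_expression <- function(n_samples, cluster_map,
                                within_cluster_rho = 0.9, noise_sd = 1,
                                seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2 (correlation undefined)")
  if (within_cluster_rho < 0 || within_cluster_rho > 1) {
    stop("within_cluster_rho must be in [0, 1]")
  }
  if (is.null(names(cluster_map)) || any(!nzchar(names(cluster_map)))) {
    stop("cluster_map must be named by gene id")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- names(cluster_map)
  clusters <- unique(cluster_map)
  latent <- matrix(stats::rnorm(length(clusters) * n_samples),
                   nrow = length(clusters),
                   dimnames = list(as.character(clusters), NULL))
  m <- matrix(0, nrow = length(genes), ncol = n_samples,
              dimnames = list(genes,
                              sprintf("sample%02d", seq_len(n_samples))))
  r <- within_cluster_rho
  for (g in genes) {
    eta <- stats::rnorm(n_samples)
    m[g, ] <- sqrt(r) * latent[as.character(cluster_map[[g]]), ] +
      sqrt(1 - r) * noise_sd * eta
  }
  attr(m, "cluster_map") <- cluster_map
  m
}
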