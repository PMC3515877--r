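# Run configuration and lightweight stage logging.
#
# Configuration is JSON (jsonlite) rather than YAML: the point is a
# declarative, diffable record of simulation parameters.

#' Simulation configuration
#'
#' Assembles and validates the parameter set that drives
#' \code{\link{simulate_genome_bundle}} and the downstream recovery
#' experiments.  Defaults state the emulated world: 80 resequenced
#' accessions, per-site diversity theta = 0.005 (the genome-wide
#' Arabidopsis scale), ortholog divergence t = 0.4 proposed changes per
#' codon (giving synonymous divergence near the Arabidopsis
#' thaliana/lyrata value of roughly 0.13), omega = 0.3, kappa = 2 and
#' 400-codon genes.
#'
#' @param seed Integer master seed.
#' @param n_accessions Number of accessions in the population sample.
#' @param theta_site Expected pairwise diversity per site (>= 0).
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param kappa Transition/transversion proposal weight (> 0).
#' @param branch_length_t Proposed changes per codon between ortholog pairs.
#' @param n_genes,codons_per_gene Gene count and gene length in codons.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_accessions = 80L, theta_site = 0.005,
                       omega = 0.3, kappa = 2, branch_length_t = 0.4,
                       n_genes = 10L, codons_per_gene = 400L) {
  if (theta_site < 0) stop("theta_site must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (n_accessions < 2) stop("n_accessions must be >= 2")
  if (codons_per_gene < 2) stop("codons_per_gene must be >= 2")
  structure(
    list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
         theta_site = theta_site, omega = omega, kappa = kappa,
         branch_length_t = branch_length_t, n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene)),
    class = "sim_config"
  )
}

#' Read/write a simulation configuration (JSON)
#'
#' @param path JSON file.
#' @return \code{read_sim_config}: a validated \code{sim_config};
#'   \code{write_sim_config}: \code{path}, invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run an expression with a timed log line on stderr
#'
#' @param stage Stage name for the log line.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
log_stage <- function(stage, expr) {
  t0 <- Sys.time()
  val <- force(expr)
  dt <- difftime(Sys.time(), t0, units = "secs")
  message(sprintf("[%s] %s: %.2fs", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(dt)))
  val
}
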