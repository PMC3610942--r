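#' Scan configuration
#'
#' Collects every tunable of the pipeline with the defaults used in the
#' yeast segregant analysis the method was developed on.
#'
#' @param sd_fixed Common standard deviation assumed for both (normal
#'   quantile transformed) traits in the bivariate model; default 0.97,
#'   the SD of an NQT gene at the panel's sample size (n = 109).
#' @param pa_cutoff PA pre-filter cutoff; default 45 (estimated filter
#'   sensitivity about 0.995).
#' @param min_class_size Minimum number of samples required in each of the
#'   four joint-genotype classes; default 15.
#' @param max_missing_per_gene Genes with more missing values than this
#'   (in any condition) are removed; default 10.
#' @param marker_merge_discordance Pre-scan marker merging: neighbouring
#'   markers with fewer than this many discordant calls are combined;
#'   default 5.
#' @param module_merge_discordance Post-scan merging threshold for the
#'   epistasis map; default 15.
#' @param p_threshold LR-test p-value cutoff declaring a module
#'   significant; default 1e-6.
#' @param oned_p_threshold Wilcoxon p-value below which a module gene is
#'   considered linked (1D) to a module marker and the module removed;
#'   default 1e-5.
#' @param epistasis_p_threshold Cutoff for the epistasis-vs-marginal test;
#'   default 0.05.
#' @param n_permutations Number of expression permutations used for FDR
#'   estimation; default 10.
#' @param rng_seed Base seed for every stochastic step; default 1.
#' @return A list of class \code{"scan_config"}.
#' @export
scan_config <- function(sd_fixed = 0.97,
                        pa_cutoff = 45,
                        min_class_size = 15L,
                        max_missing_per_gene = 10L,
                        marker_merge_discordance = 5L,
                        module_merge_discordance = 15L,
                        p_threshold = 1e-6,
                        oned_p_threshold = 1e-5,
                        epistasis_p_threshold = 0.05,
                        n_permutations = 10L,
                        rng_seed = 1L) {
  cfg <- list(sd_fixed = sd_fixed, pa_cutoff = pa_cutoff,
              min_class_size = as.integer(min_class_size),
              max_missing_per_gene = as.integer(max_missing_per_gene),
              marker_merge_discordance = as.integer(marker_merge_discordance),
              module_merge_discordance = as.integer(module_merge_discordance),
              p_threshold = p_threshold,
              oned_p_threshold = oned_p_threshold,
              epistasis_p_threshold = epistasis_p_threshold,
              n_permutations = as.integer(n_permutations),
              rng_seed = as.integer(rng_seed))
  if (cfg$sd_fixed <= 0) stop("sd_fixed must be > 0")
  if (cfg$pa_cutoff < 0) stop("pa_cutoff must be >= 0")
  for (f in c("min_class_size", "max_missing_per_gene",
              "marker_merge_discordance", "module_merge_discordance",
              "n_permutations")) {
    if (cfg[[f]] < 0L) stop(f, " must be non-negative")
  }
  for (f in c("p_threshold", "oned_p_threshold", "epistasis_p_threshold")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0,1)")
  }
  structure(cfg, class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config:\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read / write a scan configuration as a flat YAML document
#'
#' Command-line runs resolve their configuration from such a file; any
#' field not present keeps its \code{\link{scan_config}} default.
#'
#' @param path YAML file with a flat mapping of config fields.
#' @return \code{read_scan_config}: a \code{scan_config}.
#' @export
read_scan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(scan_config)))
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(scan_config, vals)
}

#' @rdname read_scan_config
#' @param config A \code{scan_config} to serialize.
#' @export
write_scan_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
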