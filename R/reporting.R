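#' Configuration for a full analysis run
#'
#' @param parameter_files Named character vector or list mapping setting
#'   label to a parameter JSON path, \emph{or} \code{params} may be given
#'   directly.
#' @param params Optional named list of ready \code{cea_parameters}
#'   bundles (names are setting labels); overrides
#'   \code{parameter_files}.
#' @param mode \code{"cohort"} or \code{"microsim"}.
#' @param n_individuals,seed Microsimulation size and global seed
#'   (required for microsim mode; the seed also drives the PSA).
#' @param psa_iterations Number of PSA draws (default 1000).
#' @param lambda_grid Optional CEAC threshold grid.
#' @param out_dir Output directory (created if absent).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(parameter_files = NULL, params = NULL,
                       mode = c("cohort", "microsim"),
                       n_individuals = 10000, seed = 1,
                       psa_iterations = 1000, lambda_grid = NULL,
                       out_dir = tempfile("screencea_run_")) {
  mode <- match.arg(mode)
  if (is.null(parameter_files) && is.null(params))
    stop("provide parameter_files or params")
  if (mode == "microsim" &&
      (is.null(n_individuals) || is.null(seed)))
    stop("microsim mode requires n_individuals and seed")
  structure(list(parameter_files = parameter_files, params = params,
                 mode = mode, n_individuals = n_individuals, seed = seed,
                 psa_iterations = psa_iterations, lambda_grid = lambda_grid,
                 out_dir = out_dir),
            class = "run_config")
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the complete analysis and write all tabular outputs
#'
#' For every setting in the configuration: fits the screening model,
#' writes the pairwise cost-utility table, runs the one-way sensitivity
#' analysis (tornado) and the probabilistic sensitivity analysis, writes
#' the acceptability-curve and scatter samples, exports the per-arm cohort
#' traces from the youngest stratum, and records a run manifest (seed,
#' versions, parameter hash). On any error, partial outputs are removed.
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted \code{screen_cea} objects,
#'   PSA results and the output directory.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  outfile <- function(nm) {
    f <- file.path(config$out_dir, nm)
    created <<- c(created, f)
    f
  }
  tryCatch({
    plist <- config$params
    if (is.null(plist)) {
      plist <- lapply(config$parameter_files, load_parameters)
      if (is.null(names(plist)))
        names(plist) <- vapply(plist, function(p) p$setting$label, "")
    }
    cea_rows <- list()
    tor_rows <- list()
    psa_rows <- list()
    ceac_rows <- list()
    fits <- list()
    psas <- list()
    for (lab in names(plist)) {
      t0 <- Sys.time()
      p <- plist[[lab]]
      fit <- screen_cea(p, mode = config$mode,
                        n_individuals = config$n_individuals,
                        seed = config$seed)
      fits[[lab]] <- fit
      cea_rows[[lab]] <- cbind(setting = lab, fit$comparison$table)
      say("[%s] model fitted (%.1fs)", lab,
          as.numeric(Sys.time() - t0, units = "secs"))
      t0 <- Sys.time()
      tor <- suppressWarnings(owsa(p))
      tor_rows[[lab]] <- cbind(setting = lab, as.data.frame(tor))
      say("[%s] one-way sensitivity: %d parameters (%.1fs)", lab,
          nrow(tor), as.numeric(Sys.time() - t0, units = "secs"))
      t0 <- Sys.time()
      ps <- psa(p, n_iter = config$psa_iterations, seed = config$seed)
      psas[[lab]] <- ps
      psa_rows[[lab]] <- cbind(setting = lab, ps$deltas,
                               wtp_lambda = ps$lambda)
      grid <- config$lambda_grid
      cc <- if (is.null(grid)) ceac(ps) else ceac(ps, grid)
      ceac_rows[[lab]] <- cbind(setting = lab, as.data.frame(cc))
      say("[%s] PSA: %d iterations (%.1fs)", lab, ps$n_iter,
          as.numeric(Sys.time() - t0, units = "secs"))
      for (arm in c("diagnosed", "missed", "negative")) {
        oc <- run_cohort(p, arm, start_age = min(p$baseline_population$age))
        write_num_csv(as.data.frame(oc$traces[[1]]),
                      outfile(sprintf("trace_%s_%s.csv", lab, arm)))
      }
    }
    write_num_csv(do.call(rbind, cea_rows), outfile("cea_table.csv"))
    write_num_csv(do.call(rbind, tor_rows), outfile("tornado.csv"))
    write_num_csv(do.call(rbind, psa_rows), outfile("psa_samples.csv"))
    write_num_csv(do.call(rbind, ceac_rows), outfile("ceac.csv"))
    param_hash <- vapply(names(plist), function(lab) {
      f <- tempfile(fileext = ".json")
      on.exit(unlink(f), add = TRUE)
      write_parameters(plist[[lab]], f)
      unname(tools::md5sum(f))
    }, "")
    manifest <- list(
      seed = config$seed, mode = config$mode,
      psa_iterations = config$psa_iterations,
      n_individuals = if (config$mode == "microsim")
        config$n_individuals else NULL,
      package_version = as.character(utils::packageVersion("screencea")),
      r_version = R.version.string,
      parameter_hash = as.list(param_hash),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(fits = fits, psa = psas, out_dir = config$out_dir))
  }, error = function(e) {
    unlink(created)
    stop(e)
  })
}
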