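write_tidy <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full within-region (alpha) analysis
#'
#' For every region and requested metric: build the yearly diversity series
#' (SR and SD directly; PD and QEphy via the one-species-per-group
#' randomization with median summarization), fit and AIC-rank the six
#' candidate temporal models, bootstrap the two-breakpoint piecewise fit,
#' and derive the onset/duration/rate indicators. Deterministic given
#' `seed`; per-stage failures are recorded with their region/metric context
#' rather than aborting the run.
#'
#' @param panel a `crop_panel`.
#' @param map group-species map (required for PD/QEphy).
#' @param tree dated `dated_tree` (required for PD/QEphy).
#' @param metrics metrics to analyse.
#' @param n_rep randomization replicates for PD/QEphy.
#' @param n_boot bootstrap replicates for the piecewise fit.
#' @param seed master seed; named substreams are derived per region.
#' @param out_dir optional directory for tidy output tables and a manifest.
#' @return list: `series` (named list of `diversity_series`), `models`
#'   (AIC tables), `fits` (bootstrapped piecewise fits or error strings),
#'   `indicators` (tidy indicator table), `errors`.
#' @export
run_alpha <- function(panel, map = NULL, tree = NULL,
                      metrics = c("SR", "SD", "PD", "QEphy"),
                      n_rep = 100L, n_boot = 500L, seed = 1L,
                      out_dir = NULL) {
  metrics <- match.arg(metrics, c("SR", "SD", "PD", "QEphy"),
                       several.ok = TRUE)
  need_phylo <- any(metrics %in% c("PD", "QEphy"))
  if (need_phylo && (is.null(map) || is.null(tree)))
    stop("map and tree are required for PD/QEphy")
  if (!is.null(map)) check_group_map(map, panel)
  regions <- panel_regions(panel)
  series <- list()
  for (r in regions) {
    if ("SR" %in% metrics)
      series[[paste(r, "SR", sep = "|")]] <- alpha_series(panel, r, "SR")
    if ("SD" %in% metrics)
      series[[paste(r, "SD", sep = "|")]] <- alpha_series(panel, r, "SD")
    if (need_phylo) {
      rs <- randomized_series(panel, r, tree, map, n_rep = n_rep,
                              seed = seed)
      if ("PD" %in% metrics)
        series[[paste(r, "PD", sep = "|")]] <- rs$PD
      if ("QEphy" %in% metrics)
        series[[paste(r, "QEphy", sep = "|")]] <- rs$QEphy
    }
  }
  models <- list()
  fits <- list()
  errors <- character()
  for (key in names(series)) {
    s <- series[[key]]
    sel <- tryCatch(select_model(s), error = function(e)
      conditionMessage(e))
    if (is.character(sel)) {
      errors[key] <- paste("select_model:", sel)
    } else models[[key]] <- sel$table
    bf <- tryCatch(bootstrap_piecewise(s, n_boot = n_boot,
                                       seed = region_stream_seed(seed, key)),
                   error = function(e) conditionMessage(e))
    if (is.character(bf)) errors[key] <- paste("bootstrap:", bf)
    else fits[[key]] <- bf
  }
  keys <- data.frame(region = sub("\\|.*$", "", names(fits)),
                     metric = sub("^.*\\|", "", names(fits)),
                     stringsAsFactors = FALSE)
  ind <- indicator_table(fits, keys)
  out <- list(series = series, models = models, fits = fits,
              indicators = ind, errors = errors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste("seed:", seed), paste("n_rep:", n_rep),
             paste("n_boot:", n_boot))
    write_tidy(series_table(series), file.path(out_dir, "alpha_series.tsv"),
               hdr)
    mtab <- do.call(rbind, lapply(names(models), function(k)
      cbind(key = k, models[[k]])))
    write_tidy(mtab, file.path(out_dir, "model_selection.tsv"), hdr)
    ftab <- do.call(rbind, lapply(names(fits), function(k) {
      f <- fits[[k]]
      m <- f$boot$medians
      data.frame(key = k, a = m[["a"]], b = m[["b"]], c = m[["c"]],
                 d = m[["d"]], psi1 = m[["psi1"]], psi2 = m[["psi2"]],
                 aic = m[["aic"]], r2 = m[["r2"]],
                 n_success = f$boot$n_success, n_boot = f$boot$n_boot)
    }))
    write_tidy(ftab, file.path(out_dir, "piecewise_boot.tsv"), hdr)
    write_tidy(ind, file.path(out_dir, "indicators.tsv"), hdr)
    manifest <- c(paste("cropshift", as.character(utils::packageVersion("cropshift"))),
                  paste("timestamp:", format(Sys.time())), hdr,
                  paste("regions:", length(regions)),
                  paste("metrics:", paste(metrics, collapse = ",")),
                  if (length(errors))
                    paste("error:", names(errors), errors))
    writeLines(manifest, file.path(out_dir, "alpha_manifest.txt"))
  }
  out
}

#' Run the full among-region (beta) analysis
#'
#' Bray-Curtis dissimilarities among all region-year communities, NMDS
#' ordination, PERMANOVA on region, year and their interaction, and the
#' within-year similarity trend, with sample and pair counts reported.
#'
#' @param panel a `crop_panel`.
#' @param k NMDS dimensions.
#' @param restarts NMDS random restarts.
#' @param permutations PERMANOVA permutations.
#' @param seed master seed.
#' @param run_nmds set `FALSE` to skip the ordination (the slowest stage).
#' @param out_dir optional directory for tidy output tables.
#' @return list: `dm`, `n_samples`, `n_within_year_pairs`, `nmds`,
#'   `permanova`, `trend`.
#' @export
run_beta <- function(panel, k = 2L, restarts = 20L, permutations = 999L,
                     seed = 1L, run_nmds = TRUE, out_dir = NULL) {
  dm <- dissimilarity_matrix(panel)
  keys <- dist_keys(dm)
  ord <- if (run_nmds)
    nmds(dm, k = k, restarts = restarts, seed = seed) else NULL
  perm <- permanova(dm, permutations = permutations, seed = seed)
  trend <- similarity_trend(dm)
  out <- list(dm = dm, n_samples = nrow(keys),
              n_within_year_pairs = nrow(trend$pairs),
              nmds = ord, permanova = perm, trend = trend)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste("seed:", seed), paste("permutations:", permutations),
             "year treated as numeric covariate; sequential SS",
             "trend response is Bray-Curtis dissimilarity (similarity = 1 - bc)")
    write_tidy(perm, file.path(out_dir, "permanova.tsv"), hdr)
    if (!is.null(ord))
      write_tidy(data.frame(sample = rownames(ord$coordinates),
                            ord$coordinates),
                 file.path(out_dir, "nmds_coordinates.tsv"),
                 c(hdr, paste("stress:", ord$stress)))
    write_tidy(trend$pairs, file.path(out_dir, "within_year_pairs.tsv"), hdr)
    lin <- trend$linear
    write_tidy(data.frame(slope = lin$slope, intercept = lin$intercept,
                          r2 = lin$r2, p = lin$p, n = lin$n),
               file.path(out_dir, "trend_linear.tsv"), hdr)
  }
  out
}
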