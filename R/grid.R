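## Configuration handling and the NSR x PCN grid runner.

#' Load a run configuration from YAML
#'
#' Reads a YAML file of pipeline settings (`nsr`, `pcn`, `algo`, `folds`,
#' `seed`, `min_positives`, table paths under `paths:`), interpolates
#' `${VAR}` environment-variable references in string values, and fills
#' defaults.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  interp <- function(x) {
    if (is.list(x)) return(lapply(x, interp))
    if (is.character(x) && length(x) == 1L && grepl("\\$\\{[^}]+\\}", x)) {
      m <- gregexpr("\\$\\{[^}]+\\}", x)[[1L]]
      for (ref in regmatches(x, list(m))[[1L]]) {
        var <- sub("^\\$\\{(.*)\\}$", "\\1", ref)
        x <- sub(ref, Sys.getenv(var), x, fixed = TRUE)
      }
    }
    x
  }
  cfg <- interp(cfg)
  utils::modifyList(list(nsr = 1, pcn = 300, algo = "svm", folds = 5L,
                         seed = 1L, min_positives = 10L), cfg)
}

#' Write the resolved configuration snapshot next to run outputs
#'
#' @param config Settings list.
#' @param path Output YAML path.
#' @export
write_config_snapshot <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Grid search over negative-sample ratio and PCA component number
#'
#' Runs the full pipeline once per `(nsr, pcn)` cell with a shared seed
#' and collects macro-F1 and macro-AUC. A failing cell is marked with its
#' error message instead of aborting the grid.
#'
#' @param catalog,network,ddaa As in [run_pipeline()].
#' @param config Base settings list.
#' @param nsr_values,pcn_values Non-empty numeric vectors of grid values.
#' @return Data.frame with columns `nsr`, `pcn`, `macro_f1`, `macro_auc`,
#'   `status`.
#' @export
grid_search <- function(catalog, network, ddaa, config = list(),
                        nsr_values = c(0.5, 1, 2, 3),
                        pcn_values = c(10, 50, 100, 300)) {
  stopifnot(length(nsr_values) > 0L, length(pcn_values) > 0L)
  ranked <- rank_pairs(network, catalog$drugs)
  cells <- expand.grid(nsr = nsr_values, pcn = pcn_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- utils::modifyList(config,
                             list(nsr = cells$nsr[i], pcn = cells$pcn[i]))
    res <- tryCatch({
      rep <- run_pipeline(catalog, network, ddaa, cfg, ranked)
      data.frame(nsr = cells$nsr[i], pcn = cells$pcn[i],
                 macro_f1 = rep$macro[["f1"]],
                 macro_auc = rep$macro[["auc"]],
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(nsr = cells$nsr[i], pcn = cells$pcn[i],
                 macro_f1 = NA_real_, macro_auc = NA_real_,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an evaluation report as TSV and JSON
#'
#' @param report An `eval_report`.
#' @param prefix Output path prefix; writes `<prefix>_per_adr.tsv`,
#'   `<prefix>_macro.tsv` and `<prefix>.json`.
#' @export
write_report <- function(report, prefix) {
  utils::write.table(report$per_adr, paste0(prefix, "_per_adr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  macro <- data.frame(metric = names(report$macro),
                      value = as.numeric(report$macro))
  utils::write.table(macro, paste0(prefix, "_macro.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_adr = report$per_adr,
                            macro = as.list(report$macro),
                            config = report$config[!vapply(report$config,
                                                           is.function,
                                                           logical(1))]),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}
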