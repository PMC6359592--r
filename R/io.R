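# Plate/result interchange and run configuration: strict CSV/TSV readers
# and writers, YAML config validation.

#' Read a qPCR plate CSV
#'
#' Strict reader for the plate format: required header columns `sample`,
#' `assay`, `replicate`, `cq`; optional `efficiency`. Rows with a blank or
#' non-numeric `cq` are rejected with a warning naming their line numbers.
#' Duplicated `(sample, assay, replicate)` keys trigger a warning and are
#' resolved last-wins.
#'
#' @param path CSV path.
#' @return `data.frame` of well records (possibly zero rows).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("plate file not found: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "assay", "replicate", "cq")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plate '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  cq <- suppressWarnings(as.numeric(df$cq))
  bad <- which(is.na(cq))
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with blank/non-numeric cq ",
            "in '", path, "' (line ", paste(bad + 1L, collapse = ", "), ")")
    df <- df[-bad, , drop = FALSE]
    cq <- cq[-bad]
  }
  df$cq <- cq
  key <- paste(df$sample, df$assay, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    warning("duplicated (sample, assay, replicate) key(s) in '", path,
            "'; keeping the last occurrence of each")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write records as a results TSV
#'
#' @param records `data.frame` to write.
#' @param path Output path.
#' @export
write_results_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Known configuration schema: every key a run can use, with its default.
# Unknown keys are rejected by name so typos never become silent defaults.
default_run_config <- function() {
  list(
    preset = "pc3m",
    seed = 1L,
    out_dir = NULL,
    write_fasta = FALSE,
    stages = list(threec = TRUE, expression = TRUE, chip = TRUE,
                  ddpcr = TRUE),
    qc = list(threshold_percent = 85, warn_only = FALSE),
    background = list(iterative = TRUE, z_threshold = 2,
                      scale_floor = 0.25, max_rounds = 3L),
    loops = list(min_fold_bg = 3.0, min_fold_prox = 1.5,
                 proximal_window_kb = 8)
  )
}

.merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(c(paste(c(path, ""), collapse = "/")), collapse = ""),
         paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], as.list(user[[k]]),
                                     c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Fills defaults for absent keys and rejects unknown keys by name. The
#' effective (fully merged) configuration is what [run_pipeline()] echoes
#' into its output directory.
#'
#' @param path YAML path, or a list of overrides.
#' @return The effective configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  .merge_config(default_run_config(), user)
}
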