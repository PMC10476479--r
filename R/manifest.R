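#' Write a run manifest
#'
#' Every CLI run emits one `manifest.json` recording the verb, the fully
#' resolved parameters, the seed, content digests (MD5) of the inputs, the
#' output files, the package version and the RNG contract
#' (Mersenne-Twister), so a run can be reproduced exactly from its
#' manifest alone.
#'
#' @param path Output JSON path.
#' @param command Verb name.
#' @param params Named list of resolved parameters.
#' @param seed Integer seed (or `NA`).
#' @param inputs Character vector of input files (digested).
#' @param outputs Character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, params, seed = NA_integer_,
                               inputs = character(0), outputs = character(0)) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.vector(d), basename(names(d)))
  } else {
    NULL
  }
  manifest <- list(
    command = command,
    config_echo = params,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    input_digest = digests,
    outputs = basename(outputs),
    tool_version = as.character(utils::packageVersion("maxentseg")),
    rng = list(kind = "Mersenne-Twister", normal_kind = "Inversion")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize a search result to JSON
#'
#' @param result A `search_result`.
#' @param path Output JSON path.
#' @param extra Named list merged into the report (e.g. dialect, input).
#' @return `path`, invisibly.
#' @export
write_search_report <- function(result, path, extra = list()) {
  report <- c(
    list(
      thresholds = result$best_thresholds$cuts,
      objective = result$best_value,
      base = result$base,
      method = result$method,
      evaluations = result$evaluations,
      generations = result$generations_run,
      seed = if (is.na(result$seed)) NULL else result$seed,
      n_levels = result$best_thresholds$n_levels
    ),
    extra
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(
    per_class_dice = report$per_class_dice,
    per_class_jaccard = report$per_class_jaccard,
    overall_accuracy = report$overall_accuracy,
    confusion = lapply(
      seq_len(nrow(report$confusion)),
      function(i) as.integer(report$confusion[i, ])
    ),
    matching = report$matching,
    flags = report$flags,
    threshold_error = report$threshold_error
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
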