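#' Read a delimited sgRNA/target dataset
#'
#' Expects a header with columns `sgrna`, `dna` and optionally `label`
#' (names case-insensitive; remappable via `col_map` for files using other
#' conventions). The delimiter is auto-detected (TSV default, comma
#' accepted). Rows failing validation (wrong length, bad alphabet, bad
#' label) are collected into a rejects report attached as
#' `attr(x, "rejects")`, never silently dropped. Rows whose sgRNA carries a
#' concrete base instead of the NGG wildcard at position 21 are kept but
#' counted in `attr(x, "n_concrete_p21")`.
#'
#' @param path file path
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(sgrna = "guide_seq", dna = "off_seq")`
#' @return data.frame (`sgrna`, `dna`[, `label`]) of valid records
#' @export
#' @examples
#' # a small simulator-generated (synthetic) example shipped with the package
#' path <- system.file("extdata", "synthetic_pairs_example.tsv",
#'                     package = "crisproff")
#' head(read_dataset(path))
read_dataset <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort_cf(paste("no such file:", path), "IOError")
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L) abort_cf("dataset file has no records", "EmptyInput")
  nm <- tolower(names(dt))
  names(dt) <- nm
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      hit <- which(nm == tolower(col_map[[std]]))
      if (length(hit)) names(dt)[hit[1]] <- std
    }
  }
  if (!all(c("sgrna", "dna") %in% names(dt))) {
    abort_cf("required columns sgrna/dna not found (use col_map to remap)",
             "SchemaError")
  }
  has_label <- "label" %in% names(dt)
  n <- nrow(dt)
  keep <- logical(n)
  reason <- character(n)
  sg <- character(n)
  dn <- character(n)
  lab <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      s <- normalize_sequence(dt$sgrna[i])
      d <- normalize_sequence(dt$dna[i])
      l <- NA_integer_
      if (has_label) {
        l <- suppressWarnings(as.integer(dt$label[i]))
        if (is.na(l) || !l %in% c(0L, 1L)) stop("label must be 0 or 1")
      }
      list(s = s, d = d, l = l)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      reason[i] <- res
    } else {
      keep[i] <- TRUE
      sg[i] <- res$s
      dn[i] <- res$d
      lab[i] <- res$l
    }
  }
  out <- data.frame(sgrna = sg[keep], dna = dn[keep],
                    stringsAsFactors = FALSE)
  if (has_label) out$label <- lab[keep]
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  n_concrete <- sum(substr(out$sgrna, WILDCARD_POS, WILDCARD_POS) != "N")
  if (n_concrete > 0L) {
    message(n_concrete,
            " record(s) carry a concrete base at PAM position 21 (expected wildcard N)")
  }
  if (nrow(rejects)) {
    warning(nrow(rejects), " malformed record(s) rejected; see attr(x, 'rejects')",
            call. = FALSE)
  }
  attr(out, "rejects") <- rejects
  attr(out, "n_concrete_p21") <- n_concrete
  out
}

#' Write a dataset as TSV
#'
#' @param data data.frame with `sgrna`, `dna` and optionally `label`
#' @param path output path
#' @export
write_dataset <- function(data, path) {
  data.table::fwrite(data, path, sep = "\t")
  invisible(path)
}

#' Write / read a metrics report as JSON
#'
#' @param report a [metrics_report()] object
#' @param path file path
#' @export
write_metrics <- function(report, path) {
  obj <- list(
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, f1 = report$f1, auroc = report$auroc,
    auprc = report$auprc, counts = as.list(report$counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    accuracy = obj$accuracy, precision = obj$precision %||% NA_real_,
    recall = obj$recall %||% NA_real_, f1 = obj$f1 %||% NA_real_,
    auroc = obj$auroc %||% NA_real_, auprc = obj$auprc %||% NA_real_,
    counts = unlist(obj$counts)
  ), class = "metrics_report")
}

#' Write / read a hyperparameter genome as JSON
#'
#' @param g an [genome()] object
#' @param path file path
#' @export
write_genome <- function(g, path) {
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(genome, obj)
}

#' Write / read a GA history as CSV
#'
#' The per-generation table (generation, individual, genome JSON, fitness,
#' parent indices, mutated genes, note) round-trips exactly: replaying the
#' stored seed with the same deterministic fitness reproduces it.
#'
#' @param history the `history` element of an [evolve()] result
#' @param path file path
#' @export
write_ga_history <- function(history, path) {
  data.table::fwrite(history, path)
  invisible(path)
}

#' @rdname write_ga_history
#' @export
read_ga_history <- function(path) {
  # read.csv rather than fread: the genome column holds JSON whose embedded
  # quotes are CSV-doubled on write and must be unescaped on read
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(genome = "character", parents = "character",
                                 mutated = "character", note = "character"))
}

#' Write an attribution report as TSV
#'
#' Works for [feature_importance()] tables, [region_summary()] tables and
#' [layer_attribution()] rankings; numeric columns are written at full
#' precision with a deterministic column order.
#'
#' @param table report data.frame
#' @param path file path
#' @export
write_report <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write a run manifest
#'
#' Records the command, configuration, seeds, package version, input file
#' digests and output inventory of a run -- enough to replay it.
#'
#' @param command character tag
#' @param config list of configuration values
#' @param seed integer seed
#' @param inputs character vector of input paths
#' @param outputs character vector of output paths
#' @param path manifest destination (JSON)
#' @export
write_manifest <- function(command, config, seed, inputs, outputs, path) {
  digest <- function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }
  obj <- list(
    command = command,
    version = as.character(utils::packageVersion("crisproff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = lapply(stats::setNames(inputs, inputs), digest),
    outputs = outputs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
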