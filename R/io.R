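#' Read a gene x sample expression table
#'
#' Reads a TSV/CSV with gene IDs in the first column and sample IDs in the
#' header. Duplicate gene rows are collapsed by their mean (with a warning),
#' matching the usual probe-averaging rule; duplicate sample IDs are an error.
#'
#' @param path file path (.tsv/.txt tab-separated, .csv comma-separated).
#' @param scale_tag scale of the stored values (`"raw"`, `"log2"`, `"normalized"`).
#' @param samples_as_rows set TRUE if the file is transposed (samples in rows).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = "raw", samples_as_rows = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression table needs >= 1 sample column")
  ids <- raw[[1]]
  if (anyDuplicated(colnames(raw)[-1]))
    stop("duplicate sample IDs in header of ", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s' in %s",
                 ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, colnames(raw)[-1])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("collapsing %d duplicated gene ID(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    num <- rowsum(num, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    rownames(num) <- unique(ids)
  }
  if (samples_as_rows) num <- t(num)
  expression_matrix(num, scale_tag)
}

#' Write an expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param header_comment optional comment lines written with a leading `#`.
#' @export
write_expression <- function(expr, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  utils::write.table(format(unclass(expr), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

# Roman numeral substage -> numeric stage (IA/IB -> 1 ... IV -> 4)
stage_from_substage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^STAGE\\s*", "", x)
  roman <- sub("[ABC]$", "", x)
  map <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
  out <- unname(map[roman])
  num <- suppressWarnings(as.integer(sub("[ABC]$", "", x)))
  out[is.na(out)] <- ifelse(!is.na(num[is.na(out)]) & num[is.na(out)] %in% 1:4,
                            num[is.na(out)], NA_integer_)
  out
}

#' Read a clinical TSV
#'
#' Requires `sample_id`, `os_time_days` and `os_event` columns; `stage` may be
#' numeric or a Roman substage string ("IA", "IIIB", ...) which is collapsed to
#' a whole stage. Unparseable stages become NA and the record is retained.
#' Empty strings and "NA" both denote missing.
#'
#' @param path TSV path.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "os_time_days", "os_event")
  miss <- setdiff(need, colnames(d))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  stage_raw <- if ("stage" %in% colnames(d)) d$stage else NA
  stage_num <- suppressWarnings(as.integer(stage_raw))
  stage <- ifelse(!is.na(stage_num) & stage_num %in% 1:4, stage_num,
                  stage_from_substage(stage_raw))
  get <- function(nm) if (nm %in% colnames(d)) d[[nm]] else NA
  clinical_table(sample_id = d$sample_id, stage = stage,
                 os_time_days = d$os_time_days, os_event = d$os_event,
                 age = get("age"), sex = get("sex"),
                 t_stage = get("t_stage"), n_stage = get("n_stage"),
                 m_stage = get("m_stage"),
                 substage = if ("stage" %in% colnames(d)) as.character(stage_raw) else NA)
}

#' Write a clinical table as TSV
#' @param clinical a [clinical_table()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Packaged stage-wise DEG lists for the five staging-and-survival modules
#'
#' Returns the packaged transcription of the published per-module DEG lists
#' for the stage-1-vs-2 and stage-1-vs-rest comparisons across modules M1, M3,
#' M6, M9 and M16, with hub flags (top-10% kME members) and the per-module
#' regulation direction.
#'
#' @return a data.frame with columns `module`, `color`, `comparison`, `gene`,
#'   `hub` (logical), `direction` ("up"/"down"/NA).
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_degs.tsv", package = "ratiosig",
                      mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, na.strings = "NA")
  d$hub <- d$hub == 1
  d
}

#' Read signature definitions from a 3-column TSV
#'
#' Format: columns `name`, `side` (`num` or `den`), `gene`; one gene per row.
#'
#' @param path TSV path.
#' @param invert named logical vector: signatures whose score must be negated.
#' @return a named list of [signature_def()] objects.
#' @export
read_signatures <- function(path, invert = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE)
  if (!all(c("name", "side", "gene") %in% colnames(d)))
    stop("signature TSV needs columns name, side, gene")
  if (!all(d$side %in% c("num", "den")))
    stop("signature side must be 'num' or 'den'")
  out <- lapply(split(d, d$name), function(s) {
    signature_def(s$name[1], s$gene[s$side == "num"], s$gene[s$side == "den"],
                  invert = isTRUE(unname(invert[s$name[1]])))
  })
  out[unique(d$name)]
}

#' Packaged signature fixtures
#'
#' Loads the study's 8-gene prognostic signature
#' (ATP6V0E1 + SVBP + HSDL1 + UBTD1) / (GNPNAT1 + XRCC2 + TFAP2A + PPP1R13L).
#' Comparator signatures (e.g. Song, Shedden, Soltis) are not redistributed;
#' supply them via [read_signatures()] in the same format.
#'
#' @return named list of [signature_def()] objects.
#' @export
load_signature_fixtures <- function() {
  path <- system.file("extdata", "signature_8gene.tsv", package = "ratiosig",
                      mustWork = TRUE)
  read_signatures(path)
}
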