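# Readers and writers for the trait-table and variant-FASTA dialects.

#' Read a single-cell trait table
#'
#' CSV (or TSV, by file extension) with a header row. Mandatory columns:
#' `species`, `stage`, plus either `cell_volume` or both `length` and
#' `width` (from which the spheroid volume is computed). Optional:
#' `temperature`, `macronuclear_volume`, `rdna_cnpc`, `rrna_cnpc`,
#' `replicate`. Rows failing validation (unknown stage, non-positive
#' volume, MV >= CV, negative copy numbers) are dropped with a warning
#' naming their line numbers; invalid rows are attached as the
#' `"rejected"` attribute.
#'
#' @param path File path.
#' @return Validated data.frame of cell records.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("read_trait_table(): no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("read_trait_table(): unreadable file: ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("read_trait_table(): empty table")
  if (!all(c("species", "stage") %in% names(tab))) {
    stop("read_trait_table(): missing mandatory column(s): ",
         paste(setdiff(c("species", "stage"), names(tab)), collapse = ", "))
  }
  has_dims <- all(c("length", "width") %in% names(tab))
  if (!("cell_volume" %in% names(tab)) && !has_dims) {
    stop("read_trait_table(): need cell_volume or length+width columns")
  }
  if (!("cell_volume" %in% names(tab))) tab$cell_volume <- NA_real_
  if (has_dims) {
    need <- is.na(tab$cell_volume) & !is.na(tab$length) & !is.na(tab$width) &
      tab$length > 0 & tab$width > 0
    tab$cell_volume[need] <- (pi / 6) * tab$length[need] * tab$width[need]^2
  }
  problems <- character(0)
  bad <- logical(nrow(tab))
  flag <- function(rows, why) {
    if (any(rows, na.rm = TRUE)) {
      rows[is.na(rows)] <- FALSE
      bad <<- bad | rows
      # +1 for the header line
      problems <<- c(problems, paste0("line ", which(rows) + 1L, ": ", why))
    }
  }
  flag(!(tab$stage %in% LIFE_STAGES), "unknown stage")
  flag(is.na(tab$cell_volume) | tab$cell_volume <= 0,
       "missing or non-positive cell volume")
  if ("macronuclear_volume" %in% names(tab)) {
    flag(!is.na(tab$macronuclear_volume) &
           (tab$macronuclear_volume <= 0 |
              tab$macronuclear_volume >= tab$cell_volume),
         "macronuclear volume out of range")
  }
  for (col in c("rdna_cnpc", "rrna_cnpc")) {
    if (col %in% names(tab)) {
      flag(!is.na(tab[[col]]) & tab[[col]] < 0, paste("negative", col))
    }
  }
  if (any(bad)) {
    warning("read_trait_table(): rejected ", sum(bad), " row(s):\n  ",
            paste(problems, collapse = "\n  "))
  }
  out <- tab[!bad, , drop = FALSE]
  if (nrow(out) == 0L) stop("read_trait_table(): no valid rows")
  rownames(out) <- NULL
  attr(out, "rejected") <- tab[bad, , drop = FALSE]
  out
}

#' Read a variant pool from FASTA
#'
#' Read counts are taken from a `;size=N` suffix in each header (the
#' usual dereplicated-FASTA dialect) or from a sidecar TSV (`id`,
#' `count`); records with neither default to count 1 with a warning.
#' Sequences are uppercased; non-ACGT characters raise an error naming
#' the record.
#'
#' @param path FASTA file path.
#' @param counts Optional path to a sidecar TSV with columns id, count.
#' @param cell_id,pool_type,residual_error_rate Passed to
#'   [variant_pool()].
#' @return A [variant_pool()].
#' @export
read_variant_fasta <- function(path, counts = NULL, cell_id = "cell",
                               pool_type = "rDNA",
                               residual_error_rate = 0) {
  if (!file.exists(path)) stop("read_variant_fasta(): no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("read_variant_fasta(): no records")
  ids <- names(seqs)
  seq_chr <- toupper(as.character(seqs))
  bad <- which(!grepl("^[ACGT]+$", seq_chr))
  if (length(bad)) {
    stop("read_variant_fasta(): non-ACGT characters in record(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  size_match <- regmatches(ids, regexpr(";size=[0-9]+", ids))
  n <- rep(NA_integer_, length(ids))
  has_size <- grepl(";size=[0-9]+", ids)
  n[has_size] <- as.integer(sub(";size=", "",
                                regmatches(ids, regexpr(";size=[0-9]+",
                                                        ids))))
  if (!is.null(counts)) {
    sidecar <- utils::read.table(counts, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    if (!all(c("id", "count") %in% names(sidecar))) {
      stop("read_variant_fasta(): sidecar needs columns id, count")
    }
    bare <- sub(";.*$", "", ids)
    m <- match(bare, sidecar$id)
    n[!is.na(m)] <- sidecar$count[m[!is.na(m)]]
  }
  if (anyNA(n)) {
    warning("read_variant_fasta(): ", sum(is.na(n)),
            " record(s) without counts; defaulting to 1")
    n[is.na(n)] <- 1L
  }
  variant_pool(seq_chr, n, cell_id = cell_id, pool_type = pool_type,
               residual_error_rate = residual_error_rate)
}

#' Write a variant pool to FASTA with size annotations
#'
#' @param pool A [variant_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "variant_pool"))
  v <- pool$variants
  lines <- as.vector(rbind(
    sprintf(">%s_v%d;size=%d", pool$cell_id, seq_len(nrow(v)), v$count),
    v$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fit summary as JSON
#'
#' Serialises a [power_law_fit()], [growth_model_fit()] or standard curve
#' (or a list of them) with stable key order.
#'
#' @param fit Fit object or named list of fit objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  strip <- function(f) {
    f <- unclass(f)
    f$response_values <- NULL
    if (!is.null(f$response) && is.numeric(f$response)) f$response <- NULL
    f
  }
  payload <- if (inherits(fit, c("power_law_fit", "growth_model_fit",
                                 "standard_curve"))) {
    strip(fit)
  } else {
    lapply(fit, strip)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
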