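# Reading, standardization, filtering, and deduplication of prediction
# tables and reference sets.

.ALLOWED_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                       "Br", "I", "H")
.MAX_SMILES_LENGTH <- 250L
.MAX_RINGS <- 10L

.ob_canonical <- function(x) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste(x, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  sub("\t.*$", "", lines)
}

#' Standardize SMILES strings
#'
#' Converts SMILES to a single canonical, stereochemistry-free form so that
#' identical structures always map to identical strings. Stereo descriptors
#' (tetrahedral marks and double-bond direction symbols) are removed before
#' canonicalization; the result is idempotent under re-standardization.
#'
#' @param x character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as `x`.
#' @examples
#' standardizeSmiles(c("OCC", "CCO"))          # identical output
#' standardizeSmiles("C[C@H](O)CC")            # stereo stripped
#' @export
standardizeSmiles <- function(x) {
  if (!is.character(x) || length(x) == 0)
    stop("x must be a non-empty character vector")
  if (any(is.na(x) | !nzchar(x)))
    stop(errorCondition("empty or NA SMILES input",
                        class = c("molUQ_parse_error", "error")))
  stripped <- gsub("[@/\\\\]", "", x)
  # OpenBabel silently drops unparsable molecules from batch conversion;
  # fall back to one-at-a-time to attribute the failure.
  can <- .ob_canonical(stripped)
  if (length(can) != length(x) || any(!nzchar(can))) {
    can <- vapply(seq_along(stripped), function(i) {
      ci <- .ob_canonical(stripped[i])
      if (length(ci) != 1 || !nzchar(ci)) .parse_error(x[i], "invalid SMILES")
      ci
    }, character(1))
  }
  unname(can)
}

#' Filter molecules to the supported chemical space
#'
#' Applies the data-preparation rules used before featurization: molecules
#' with 10 or more rings (smallest set of smallest rings), a SMILES
#' representation longer than 250 characters, or elements outside
#' B, C, N, O, F, Si, P, S, Cl, Br, I (hydrogen implicit) are rejected.
#' Filtering is total: unparsable entries are rejected with reason
#' `"parse"` rather than raising.
#'
#' @param x character vector of SMILES or a [PredictionSet-class].
#' @return list with `kept` (same type as `x`) and `rejected`
#'   (data.frame of smiles and the violated rule: length, element, rings,
#'   or parse).
#' @examples
#' filterSupported(c("CCO", "CC[Se]C", "c1ccccc1"))
#' @export
filterSupported <- function(x) {
  smi <- if (is(x, "PredictionSet")) smiles(x) else as.character(x)
  reason <- rep(NA_character_, length(smi))
  for (i in seq_along(smi)) {
    if (nchar(smi[i]) > .MAX_SMILES_LENGTH) {
      reason[i] <- "length"
      next
    }
    tok <- tryCatch(tokenizeSmiles(smi[i]), error = function(e) NULL)
    if (is.null(tok)) {
      reason[i] <- "parse"
    } else if (!all(tok$elements %in% .ALLOWED_ELEMENTS)) {
      reason[i] <- "element"
    } else if (tok$nRings >= .MAX_RINGS) {
      reason[i] <- "rings"
    }
  }
  keep <- is.na(reason)
  kept <- if (is(x, "PredictionSet")) x[which(keep)] else smi[keep]
  list(kept = kept,
       rejected = data.frame(smiles = smi[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Deduplicate molecules by canonical SMILES
#'
#' When a SMILES occurs several times, exactly one record is retained,
#' chosen uniformly at random under `seed`; the output order follows the
#' first occurrence of each retained SMILES and is deterministic given the
#' seed.
#'
#' @param x a [PredictionSet-class] or character vector of SMILES.
#' @param seed integer seed for the random choice among duplicates.
#' @return object of the same type as `x` with unique SMILES.
#' @export
deduplicateEntries <- function(x, seed = 1L) {
  smi <- if (is(x, "PredictionSet")) smiles(x) else as.character(x)
  pick <- withSeed(seed, {
    vapply(split(seq_along(smi), factor(smi, levels = unique(smi))),
           function(ix) if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
           integer(1))
  })
  pick <- sort(unname(pick))
  if (is(x, "PredictionSet")) x[pick] else smi[pick]
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.table_error <- function(msg, row = NULL, col = NULL) {
  loc <- c(if (!is.null(row)) sprintf("row %d", row),
           if (!is.null(col)) sprintf("column '%s'", col))
  if (length(loc)) msg <- paste0(msg, " (", paste(loc, collapse = ", "), ")")
  stop(errorCondition(msg, class = c("molUQ_table_error", "error")))
}

#' Read a prediction table
#'
#' Reads a CSV with columns `smiles,y_true,pred_1..pred_m[,fold]` into a
#' [PredictionSet-class]. SMILES are standardized on read (set
#' `standardize = FALSE` for already-canonical tables). The 250-character
#' length rule of [filterSupported()] refers to the raw input SMILES, so
#' callers wanting the full preparation pipeline should filter before
#' standardizing; `readPredictionTable` performs no filtering itself.
#'
#' @param path CSV file path (comma-separated, UTF-8, "." decimal, header
#'   required).
#' @param mExpected optional integer; error when the number of `pred_`
#'   columns differs.
#' @param standardize logical, standardize SMILES after reading.
#' @return a [PredictionSet-class].
#' @export
readPredictionTable <- function(path, mExpected = NULL, standardize = TRUE) {
  if (!file.exists(path)) .table_error(sprintf("file '%s' not found", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("smiles", "y_true")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .table_error(paste("missing required column(s):",
                       paste(miss, collapse = ", ")))
  predCols <- grep("^pred_[0-9]+$", names(df), value = TRUE)
  if (length(predCols) == 0) .table_error("no pred_<i> columns found")
  predCols <- predCols[order(as.integer(sub("^pred_", "", predCols)))]
  if (!is.null(mExpected) && length(predCols) != mExpected)
    .table_error(sprintf("expected %d prediction columns, found %d",
                         mExpected, length(predCols)))
  for (cl in c("y_true", predCols)) {
    v <- df[[cl]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) .table_error("non-numeric or missing value",
                                  row = bad[1], col = cl)
    df[[cl]] <- v
  }
  fold <- if ("fold" %in% names(df)) {
    f <- suppressWarnings(as.integer(df$fold))
    bad <- which(is.na(f) & !is.na(df$fold))
    if (length(bad)) .table_error("non-integer fold value", row = bad[1],
                                  col = "fold")
    f
  } else NULL
  smi <- as.character(df$smiles)
  if (standardize) smi <- standardizeSmiles(smi)
  PredictionSet(smi, df$y_true, as.matrix(df[, predCols, drop = FALSE]),
                foldId = fold)
}

#' Write a prediction table
#'
#' Inverse of [readPredictionTable()]: writes `smiles,y_true,pred_*`
#' (and `fold` when assigned) as CSV.
#'
#' @param x a [PredictionSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePredictionTable <- function(x, path) {
  stopifnot(is(x, "PredictionSet"))
  df <- data.frame(smiles = smiles(x), y_true = yTrue(x),
                   stringsAsFactors = FALSE)
  preds <- predictions(x)
  colnames(preds) <- paste0("pred_", seq_len(ncol(preds)))
  df <- cbind(df, as.data.frame(preds))
  if (any(!is.na(foldId(x)))) df$fold <- foldId(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference set of SMILES
#'
#' Accepts either a plain-text file with one SMILES per line or a CSV with
#' a `smiles` column.
#'
#' @param path input file.
#' @param standardize logical, standardize on read.
#' @return character vector of SMILES.
#' @export
readReferenceSmiles <- function(path, standardize = TRUE) {
  if (!file.exists(path)) .table_error(sprintf("file '%s' not found", path))
  first <- readLines(path, n = 1L)
  smi <- if (grepl(",", first) || grepl("^smiles$", trimws(first))) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) .table_error("no 'smiles' column in CSV")
    as.character(df$smiles)
  } else {
    lines <- trimws(readLines(path))
    lines[nzchar(lines)]
  }
  if (standardize) smi <- standardizeSmiles(smi)
  smi
}
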