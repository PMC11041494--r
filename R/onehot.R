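# One-hot encoding with a federated category vocabulary. Clients exchange
# only the *sets* of levels they observe; the union (deterministically
# sorted) defines the indicator columns every client emits, so a client that
# never saw a level still produces its all-zero column and all clients share
# one schema. No reference level is dropped: the ridge-style regularizer
# absorbs the collinearity, and keeping all levels makes the encoding
# independent of client ordering.

#' Build a one-hot encoder from per-client tables
#'
#' @param tables list of data.frames (one per client) sharing a column schema.
#' @param categorical_columns character vector of columns to encode.
#' @return an object of class `onehot_encoder` holding the sorted federated
#'   level union per column.
#' @export
onehot_encoder <- function(tables, categorical_columns) {
  if (length(categorical_columns) == 0L) {
    return(structure(list(levels = list()), class = "onehot_encoder"))
  }
  for (tab in tables) {
    missing <- setdiff(categorical_columns, names(tab))
    if (length(missing) > 0L) {
      stop_invalid("categorical column(s) not present: ",
                   paste(missing, collapse = ", "))
    }
  }
  levels <- lapply(categorical_columns, function(col) {
    vals <- unique(unlist(lapply(tables, function(tab) as.character(tab[[col]]))))
    sort_levels(vals)
  })
  names(levels) <- categorical_columns
  structure(list(levels = levels), class = "onehot_encoder")
}

# Numeric-looking level sets sort numerically, otherwise C-locale
# lexicographic; either way the order is deterministic across clients and
# platforms.
sort_levels <- function(vals) {
  num <- suppressWarnings(as.numeric(vals))
  if (!anyNA(num)) vals[order(num)] else sort(vals, method = "radix")
}

#' Apply a one-hot encoder to a client table
#'
#' Each categorical column is replaced, in place, by its indicator columns
#' (named `column.level`). Columns with exactly two levels collapse to a
#' single 0/1 indicator of the second level. Values outside the encoder's
#' vocabulary yield all-zero indicator rows and a warning.
#'
#' @param encoder an [onehot_encoder()].
#' @param table a data.frame.
#' @return the encoded data.frame; all indicator columns are numeric.
#' @export
apply_onehot <- function(encoder, table) {
  for (col in names(encoder$levels)) {
    lv <- encoder$levels[[col]]
    vals <- as.character(table[[col]])
    unseen <- !(vals %in% lv)
    if (any(unseen)) {
      warning("column '", col, "': ", sum(unseen),
              " value(s) outside the encoder vocabulary; emitting zero rows",
              call. = FALSE)
    }
    block <- if (length(lv) == 2L) {
      stats::setNames(data.frame(as.numeric(vals == lv[2L])),
                      paste(col, lv[2L], sep = "."))
    } else {
      cols <- lapply(lv, function(l) as.numeric(vals == l))
      stats::setNames(as.data.frame(cols), paste(col, lv, sep = "."))
    }
    pos <- match(col, names(table))
    table <- cbind(table[, seq_len(pos - 1L), drop = FALSE], block,
                   table[, -seq_len(pos), drop = FALSE])
  }
  table
}
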