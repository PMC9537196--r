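# Internal helpers shared across modules.

#' Sanitize identifiers for downstream SBML/NMODL use
#'
#' Maps arbitrary strings to identifiers matching `[A-Za-z_][A-Za-z0-9_]*`.
#' Invalid characters become `_`; identifiers starting with a digit gain a
#' leading `x`; collisions produced by the mapping get a numeric suffix.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of valid, unique identifiers (same length).
#' @export
sanitize_ids <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", as.character(x))
  bad <- grepl("^[0-9]", out)
  out[bad] <- paste0("x", out[bad])
  out[out == ""] <- "x"
  # resolve collisions deterministically with numeric suffixes
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))
    for (i in d) {
      k <- 1L
      repeat {
        cand <- paste0(out[i], "_", k)
        if (!cand %in% out) break
        k <- k + 1L
      }
      out[i] <- cand
    }
  }
  out
}

is_valid_id <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

# Numeric parser for SBtab cells. Strips thousands separators ("136,817.521")
# when strip_separators is TRUE; returns NA for non-numeric strings.
sbtab_numeric <- function(x, strip_separators = TRUE) {
  x <- as.character(x)
  if (strip_separators) {
    # strip commas used as digit-group separators, not decimal commas
    x <- gsub("(?<=[0-9]),(?=[0-9]{3}(\\D|$))", "", x, perl = TRUE)
  }
  suppressWarnings(as.numeric(x))
}

# Deterministic, locale-independent rendering of a column for TSV output.
format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  } else {
    y <- as.character(x)
    y[is.na(y)] <- ""
    y
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

abort_sbtab <- function(msg, class) {
  stop(structure(class = c(class, "sbtabflow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(gcd2, v)
}
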