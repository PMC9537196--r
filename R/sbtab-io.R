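# SBtab document input/output.
#
# An SBtab document is a set of tables (Compartment, Compound, Reaction,
# Parameter, Expression, Input, Output, Experiments, plus per-experiment
# data tables E0, E1, ...). On disk each table is a TSV file whose first
# line is a declaration ("!!SBtab TableName='...' ...") and whose second
# line holds "!"-prefixed column headers. A single .xlsx workbook with one
# sheet per table is supported read-only.

new_sbtab_document <- function(tables = list(), meta = list(), source = character()) {
  structure(list(tables = tables, meta = meta, source = source),
            class = "sbtab_document")
}

#' @export
print.sbtab_document <- function(x, ...) {
  cat("SBtab document with", length(x$tables), "table(s)\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-14s %4d row(s), %d column(s)\n", nm,
                nrow(x$tables[[nm]]), ncol(x$tables[[nm]])))
  }
  invisible(x)
}

parse_declaration <- function(line, file = "<memory>") {
  if (!startsWith(trimws(line), "!!SBtab")) {
    abort_sbtab(sprintf("file '%s' does not start with an '!!SBtab' declaration line", file),
                "sbtab_format_error")
  }
  # key='value' or key="value" pairs
  m <- gregexpr("([A-Za-z][A-Za-z0-9]*)=('[^']*'|\"[^\"]*\")", line)[[1]]
  attrs <- list()
  if (m[1] != -1) {
    pieces <- regmatches(line, gregexpr("([A-Za-z][A-Za-z0-9]*)=('[^']*'|\"[^\"]*\")", line))[[1]]
    for (p in pieces) {
      key <- sub("=.*$", "", p)
      val <- sub("^[^=]*=", "", p)
      attrs[[key]] <- substr(val, 2, nchar(val) - 1)
    }
  }
  attrs
}

# Convert character columns that are wholly numeric (ignoring blanks) to
# numeric, honouring the thousands-separator dialect flag.
type_columns <- function(df, strip_separators = TRUE) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    nonblank <- !is.na(col) & nzchar(trimws(col))
    if (!any(nonblank)) next
    num <- sbtab_numeric(col[nonblank], strip_separators)
    if (!anyNA(num)) {
      full <- rep(NA_real_, length(col))
      full[nonblank] <- num
      df[[j]] <- full
    }
  }
  df
}

read_sbtab_tsv_one <- function(path, strip_separators = TRUE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 2]
  if (length(lines) < 2) {
    abort_sbtab(sprintf("file '%s' is too short to be an SBtab table", path),
                "sbtab_format_error")
  }
  attrs <- parse_declaration(lines[1], path)
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (!any(startsWith(header, "!"))) {
    abort_sbtab(sprintf("file '%s': second line holds no '!'-prefixed column headers", path),
                "sbtab_format_error")
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  cells <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  ncol <- length(header)
  df <- as.data.frame(
    lapply(seq_len(ncol), function(j) {
      vapply(cells, function(r) if (j <= length(r)) r[j] else "", character(1))
    }),
    stringsAsFactors = FALSE, optional = TRUE
  )
  names(df) <- header
  df <- type_columns(df, strip_separators)
  list(attrs = attrs, table = df)
}

read_sbtab_xlsx <- function(path, strip_separators = TRUE) {
  sheets <- readxl::excel_sheets(path)
  out <- list()
  for (sh in sheets) {
    raw <- suppressMessages(readxl::read_excel(path, sheet = sh, col_names = FALSE,
                                               col_types = "text"))
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
    if (nrow(raw) < 2) {
      abort_sbtab(sprintf("sheet '%s' of '%s' is too short to be an SBtab table", sh, path),
                  "sbtab_format_error")
    }
    attrs <- parse_declaration(as.character(raw[1, 1]), paste0(path, "#", sh))
    header <- trimws(as.character(unlist(raw[2, ])))
    keep <- nzchar(header) & !is.na(header)
    header <- header[keep]
    df <- raw[-(1:2), keep, drop = FALSE]
    names(df) <- header
    df[] <- lapply(df, function(col) { col[is.na(col)] <- ""; as.character(col) })
    rownames(df) <- NULL
    df <- type_columns(df, strip_separators)
    out[[length(out) + 1L]] <- list(attrs = attrs, table = df, sheet = sh)
  }
  out
}

#' Read an SBtab model+data document
#'
#' Reads either a set of SBtab TSV files or a single `.xlsx` workbook (one
#' sheet per table) into an `sbtab_document`. Each table must begin with an
#' `!!SBtab` declaration line naming at least its `TableName`, followed by a
#' row of `!`-prefixed column headers. Unknown tables and columns are kept
#' verbatim so that extensions to the format survive a round trip.
#'
#' @param paths character vector: one `.xlsx` path, or one or more `.tsv`
#'   paths (a directory is expanded to the `.tsv` files it contains).
#' @param strip_separators strip thousands separators (`"136,817.521"`)
#'   during numeric parsing. Default `TRUE`.
#' @return an object of class `sbtab_document`: a named, ordered list of
#'   tables (`$tables`), per-table declaration attributes (`$meta`) and file
#'   provenance (`$source`).
#' @seealso [write_sbtab()], [validate_sbtab()]
#' @export
read_sbtab <- function(paths, strip_separators = TRUE) {
  paths <- as.character(paths)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.tsv$", full.names = TRUE))
  }
  if (!length(paths)) abort_sbtab("no tables found", "sbtab_format_error")
  tables <- list(); meta <- list()
  add_table <- function(attrs, df, src) {
    nm <- attrs[["TableName"]] %||% attrs[["TableID"]] %||%
      tools::file_path_sans_ext(basename(src))
    if (nm %in% names(tables)) {
      abort_sbtab(sprintf("duplicate table name '%s' (from '%s')", nm, src),
                  "sbtab_conflict_error")
    }
    if ("!ID" %in% names(df)) {
      ids <- df[["!ID"]]
      if (anyDuplicated(ids[nzchar(as.character(ids))])) {
        abort_sbtab(sprintf("table '%s': duplicate !ID value(s): %s", nm,
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                    "sbtab_validation_error")
      }
    }
    tables[[nm]] <<- df
    meta[[nm]] <<- attrs
  }
  for (p in paths) {
    if (grepl("\\.xlsx$", p, ignore.case = TRUE)) {
      for (entry in read_sbtab_xlsx(p, strip_separators)) {
        add_table(entry$attrs, entry$table, paste0(p, "#", entry$sheet))
      }
    } else {
      entry <- read_sbtab_tsv_one(p, strip_separators)
      add_table(entry$attrs, entry$table, p)
    }
  }
  if (!length(tables)) abort_sbtab("no tables found", "sbtab_format_error")
  new_sbtab_document(tables, meta, source = paths)
}

declaration_line <- function(name, attrs) {
  attrs[["TableName"]] <- attrs[["TableName"]] %||% name
  attrs[["TableType"]] <- attrs[["TableType"]] %||% "Quantity"
  if (is.null(attrs[["SBtabVersion"]])) attrs[["SBtabVersion"]] <- "1.0"
  paste0("!!SBtab ", paste(sprintf("%s='%s'", names(attrs), unlist(attrs)),
                           collapse = " "))
}

#' Write an SBtab document as a TSV file set
#'
#' Emits one TSV file per table into `target` (created if needed), each with
#' its declaration line and `!`-prefixed header row. The writer is lossless
#' for all stored columns and byte-stable for identical inputs.
#'
#' @param doc an `sbtab_document`.
#' @param target directory to write into.
#' @return invisibly, the character vector of files written.
#' @export
write_sbtab <- function(doc, target) {
  stopifnot(inherits(doc, "sbtab_document"))
  if (!dir.exists(target)) {
    ok <- dir.create(target, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_sbtab(sprintf("cannot create target directory '%s'", target),
                         "sbtab_io_error")
  }
  written <- character()
  for (nm in names(doc$tables)) {
    df <- doc$tables[[nm]]
    path <- file.path(target, paste0(nm, ".tsv"))
    lines <- c(declaration_line(nm, doc$meta[[nm]] %||% list()),
               paste(names(df), collapse = "\t"))
    if (nrow(df)) {
      cols <- lapply(df, format_cell)
      lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
    }
    con <- file(path, open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    written <- c(written, path)
  }
  invisible(written)
}

model_tables_required <- c("Compound", "Reaction", "Parameter")

finding <- function(severity, table, row, message) {
  data.frame(severity = severity, table = table, row = row, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(), table = character(), row = integer(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate an SBtab document
#'
#' Checks model completeness (Compound, Reaction and Parameter tables
#' present), identifier syntax, resolution of all cross-references
#' (kinetic-law symbols, reaction formulas, compartments, experiment
#' overrides, output formulas) and data-table well-formedness (strictly
#' increasing time columns, positive SD columns). Findings are data, not
#' errors: an empty result means the document is model-complete.
#'
#' @param doc an `sbtab_document`.
#' @return a data frame of findings with columns `severity`, `table`,
#'   `row`, `message`; zero rows when the document is valid.
#' @export
validate_sbtab <- function(doc) {
  stopifnot(inherits(doc, "sbtab_document"))
  out <- no_findings()
  push <- function(...) out <<- rbind(out, finding(...))

  for (nm in model_tables_required) {
    if (!nm %in% names(doc$tables)) {
      push("error", nm, NA_integer_, sprintf("required table '%s' is missing", nm))
    }
  }
  ids_of <- function(tab) {
    df <- doc$tables[[tab]]
    if (is.null(df) || !"!ID" %in% names(df)) character() else as.character(df[["!ID"]])
  }
  compounds    <- ids_of("Compound")
  params       <- ids_of("Parameter")
  compartments <- ids_of("Compartment")
  inputs       <- ids_of("Input")
  expressions  <- ids_of("Expression")
  known_symbols <- c(compounds, params, compartments, inputs, expressions,
                     "t", "time")

  for (tab in c("Compound", "Parameter", "Reaction", "Compartment", "Input")) {
    ids <- ids_of(tab)
    bad <- which(!is_valid_id(ids))
    for (i in bad) {
      push("error", tab, i, sprintf("identifier '%s' is not a valid id", ids[i]))
    }
  }

  rx <- doc$tables[["Reaction"]]
  if (!is.null(rx) && nrow(rx)) {
    for (i in seq_len(nrow(rx))) {
      frm <- as.character(rx[["!ReactionFormula"]][i] %||% "")
      if (nzchar(frm)) {
        parsed <- tryCatch(parse_reaction_formula(frm), error = function(e) e)
        if (inherits(parsed, "error")) {
          push("error", "Reaction", i, conditionMessage(parsed))
        } else {
          unk <- setdiff(c(names(parsed$reactants), names(parsed$products)), compounds)
          if (length(unk)) {
            push("error", "Reaction", i,
                 sprintf("reaction '%s': undeclared species in formula: %s",
                         rx[["!ID"]][i], paste(unk, collapse = ", ")))
          }
        }
      } else {
        push("error", "Reaction", i,
             sprintf("reaction '%s': empty !ReactionFormula", rx[["!ID"]][i]))
      }
      kl <- as.character(rx[["!KineticLaw"]][i] %||% "")
      if (nzchar(kl)) {
        err <- tryCatch({ parse_rate_expression(kl, known_symbols); NULL },
                        error = function(e) conditionMessage(e))
        if (!is.null(err)) push("error", "Reaction", i,
                                sprintf("reaction '%s': %s", rx[["!ID"]][i], err))
      }
      loc <- as.character(rx[["!Location"]][i] %||% "")
      if (nzchar(loc) && length(compartments) && !loc %in% compartments) {
        push("error", "Reaction", i,
             sprintf("reaction '%s': unknown compartment '%s'", rx[["!ID"]][i], loc))
      }
    }
  }

  cp <- doc$tables[["Compound"]]
  if (!is.null(cp) && "!Location" %in% names(cp) && length(compartments)) {
    bad <- which(nzchar(as.character(cp[["!Location"]])) &
                   !as.character(cp[["!Location"]]) %in% compartments)
    for (i in bad) push("error", "Compound", i,
                        sprintf("compound '%s': unknown compartment '%s'",
                                cp[["!ID"]][i], cp[["!Location"]][i]))
  }

  ex <- doc$tables[["Expression"]]
  if (!is.null(ex) && nrow(ex)) {
    for (i in seq_len(nrow(ex))) {
      fml <- as.character(ex[["!Formula"]][i] %||% "")
      err <- tryCatch({ parse_rate_expression(fml, known_symbols); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) push("error", "Expression", i, err)
    }
  }

  outp <- doc$tables[["Output"]]
  if (!is.null(outp) && nrow(outp)) {
    for (i in seq_len(nrow(outp))) {
      fml <- as.character(outp[["!Formula"]][i] %||% "")
      err <- tryCatch({ parse_rate_expression(fml, known_symbols); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) push("error", "Output", i, err)
    }
  }

  exps <- doc$tables[["Experiments"]]
  if (!is.null(exps) && nrow(exps)) {
    over <- grep("^>", names(exps), value = TRUE)
    for (cn in over) {
      ref <- sub("^>", "", cn)
      ref_base <- sub(":.*$", "", ref)
      if (!(ref_base %in% c(compounds, inputs))) {
        push("error", "Experiments", NA_integer_,
             sprintf("override column '%s' references neither an Input nor a Compound", cn))
      }
    }
    eids <- as.character(exps[["!ID"]])
    for (eid in eids) {
      if (eid %in% names(doc$tables)) {
        dt <- doc$tables[[eid]]
        tcol <- dt[["!Time"]]
        if (!is.null(tcol)) {
          tv <- sbtab_numeric(tcol)
          if (any(diff(tv) <= 0)) {
            push("error", eid, which(diff(tv) <= 0)[1] + 1L,
                 "time column is not strictly increasing")
          }
        }
        sdcols <- grep("^SD_", names(dt), value = TRUE)
        for (sc in sdcols) {
          sv <- sbtab_numeric(dt[[sc]])
          if (any(!is.na(sv) & sv <= 0)) {
            push("error", eid, which(sv <= 0)[1],
                 sprintf("column '%s' contains non-positive SD values", sc))
          }
        }
      }
    }
  }
  out
}

#' Extract a typed data table from an experiment sheet
#'
#' Turns a raw per-experiment SBtab data table (columns `!Time`, `>Y0`,
#' `SD_Y0`, ...) into a list with the measurement matrix `Y`, the allowed
#' per-point mismatch `tau` (standard-deviation columns, defaulting to 1
#' where absent), the time grid and the output ids.
#'
#' @param doc an `sbtab_document`.
#' @param experiment_id name of the data table (e.g. `"E0"`).
#' @return list with `times`, `Y`, `tau` (matrices timepoints x outputs) and
#'   `output_ids`.
#' @export
sbtab_data_table <- function(doc, experiment_id) {
  df <- doc$tables[[experiment_id]]
  if (is.null(df)) abort_sbtab(sprintf("no data table '%s'", experiment_id),
                               "sbtab_validation_error")
  times <- sbtab_numeric(df[["!Time"]])
  ycols <- grep("^>", names(df), value = TRUE)
  output_ids <- sub("^>", "", ycols)
  Y <- sapply(ycols, function(cn) sbtab_numeric(df[[cn]]))
  Y <- matrix(Y, nrow = nrow(df), dimnames = list(NULL, output_ids))
  tau <- matrix(1, nrow = nrow(df), ncol = length(output_ids),
                dimnames = list(NULL, output_ids))
  for (k in seq_along(output_ids)) {
    sc <- paste0("SD_", output_ids[k])
    if (sc %in% names(df)) {
      sv <- sbtab_numeric(df[[sc]])
      tau[, k] <- ifelse(is.na(sv), 1, sv)
    }
  }
  if (any(diff(times) <= 0)) {
    abort_sbtab(sprintf("data table '%s': times not strictly increasing", experiment_id),
                "sbtab_validation_error")
  }
  if (any(tau <= 0)) {
    abort_sbtab(sprintf("data table '%s': non-positive tau", experiment_id),
                "sbtab_validation_error")
  }
  list(times = times, Y = Y, tau = tau, output_ids = output_ids)
}
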