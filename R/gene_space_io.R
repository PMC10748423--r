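#' screenra: rank-aggregation meta-analysis of genetic screens
#'
#' Tools to combine candidate tables from independent genetic screens with
#' heterogeneous genome coverage into one aggregated candidate ranking, and
#' to interrogate that ranking by overlap counting, overrepresentation
#' analysis, novelty annotation and preranked gene set enrichment analysis.
#' A synthetic-data generator with planted ground truth makes every stage
#' testable without external downloads.
#'
#' @keywords internal
"_PACKAGE"

#' Canonicalize a gene symbol
#'
#' Harmonizes gene symbols to a single canonical form so that, e.g., a mouse
#' symbol (`Aak1`) and its table- or human-style counterpart (`AAK1`) compare
#' equal. The canonical form is the whitespace-trimmed, upper-cased symbol.
#' True ortholog mapping is deliberately out of scope; case-folded symbol
#' identity is the stand-in used throughout the package.
#'
#' The transformation is idempotent: `harmonize_symbol(harmonize_symbol(s))`
#' equals `harmonize_symbol(s)`.
#'
#' @param symbol character vector of gene symbols; elements must be non-empty
#'   after whitespace trimming.
#' @return character vector of harmonized symbols.
#' @examples
#' harmonize_symbol(c("Aak1", " sprr1b "))
#' @export
harmonize_symbol <- function(symbol) {
  if (!is.character(symbol)) {
    stop("'symbol' must be a character vector", call. = FALSE)
  }
  out <- toupper(trimws(symbol))
  if (length(out) && any(is.na(out) | !nzchar(out))) {
    stop("empty gene symbol", call. = FALSE)
  }
  out
}

#' Load the underlying gene space
#'
#' Reads the fixed universe of gene symbols over which aggregation and
#' enrichment backgrounds are defined (e.g. a GRCm38 symbol set), one symbol
#' per line. Blank lines and lines starting with `#` are ignored. Symbols are
#' harmonized via [harmonize_symbol()] and de-duplicated preserving
#' first-seen order; duplicates trigger a warning with a count.
#'
#' @param path path to a plain-text file, one gene symbol per line.
#' @return a `gene_space`: character vector of unique harmonized symbols with
#'   class `"gene_space"`.
#' @export
load_gene_space <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("empty gene space: ", path, call. = FALSE)
  }
  as_gene_space(lines)
}

#' Construct a gene space from a character vector
#'
#' @param symbols character vector of gene symbols (harmonized internally).
#' @return a `gene_space` object.
#' @export
as_gene_space <- function(symbols) {
  symbols <- harmonize_symbol(symbols)
  dup <- duplicated(symbols)
  if (any(dup)) {
    warning(sum(dup), " duplicate symbol(s) removed from gene space",
            call. = FALSE)
    symbols <- symbols[!dup]
  }
  structure(symbols, class = "gene_space")
}

#' @export
print.gene_space <- function(x, ...) {
  cat("gene_space with", length(x), "symbols:",
      paste(utils::head(unclass(x)), collapse = ", "),
      if (length(x) > 6L) "..." else "", "\n")
  invisible(x)
}

# Sniff the field separator of a delimited text file from its header line.
sniff_sep <- function(path) {
  header <- readLines(path, n = 50L, warn = FALSE)
  header <- header[nzchar(header) & !startsWith(header, "#")]
  if (length(header) == 0L) stop("empty table: ", path, call. = FALSE)
  if (grepl("\t", header[1L], fixed = TRUE)) "\t" else ","
}

#' Load one screen's candidate table
#'
#' Reads a delimited (TSV or CSV, auto-detected from the header) candidate
#' table from one genetic screen: every gene the screen tested, with the
#' significance measure chosen by the screen's original authors (p-value or
#' FDR, on \[0,1\]). Rows with an empty measure cell are recorded as
#' tested-but-unmeasured: the gene was in the screen's library but no
#' significance value was reported, which downstream ranks as "tested but not
#' significant".
#'
#' @param path path to the table; `#` comment lines are ignored.
#' @param screen_id identifier for the screen (free text).
#' @param measure_column name of the significance-measure column.
#' @param gene_column name of the gene-symbol column.
#' @param effect_column optional name of an effect-size column used only to
#'   break ties in significance when ranking.
#' @param direction_column optional column with predicted direction labels
#'   (e.g. `GOF`/`LOF`).
#' @param measure_name label for the measure (e.g. `"p"`, `"FDR"`); defaults
#'   to `measure_column`.
#' @return a `screen_result` object: list with `screen_id`, `measure_name`,
#'   `measures` (named numeric over tested genes, `NA` where unmeasured),
#'   `tested` (character), and optional `effects`/`direction`.
#' @export
load_screen_table <- function(path, screen_id,
                              measure_column = "p",
                              gene_column = "gene",
                              effect_column = NULL,
                              direction_column = NULL,
                              measure_name = measure_column) {
  stopifnot(file.exists(path))
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c(gene_column, measure_column, effect_column, direction_column)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("unknown column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  genes <- harmonize_symbol(tab[[gene_column]])
  raw <- trimws(tab[[measure_column]])
  measures <- suppressWarnings(as.numeric(raw))
  unparsed <- nzchar(raw) & !is.na(raw) & is.na(measures)
  if (any(unparsed)) {
    stop("non-numeric significance measure at row ",
         which(unparsed)[1L], ": '", raw[which(unparsed)[1L]], "'",
         call. = FALSE)
  }
  bad <- !is.na(measures) & (measures < 0 | measures > 1)
  if (any(bad)) {
    stop("significance measure outside [0,1] at row ", which(bad)[1L],
         ": ", measures[which(bad)[1L]], call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)), " duplicate gene(s) in screen '",
            screen_id, "'; keeping the smallest measure per gene",
            call. = FALSE)
    ord <- order(genes, measures, na.last = TRUE)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)
    tab <- tab[keep, , drop = FALSE]
    measures <- measures[keep]
    genes <- genes[keep]
  }
  names(measures) <- genes
  res <- new_screen_result(screen_id = screen_id, measure_name = measure_name,
                           measures = measures)
  if (!is.null(effect_column)) {
    eff <- suppressWarnings(as.numeric(tab[[effect_column]]))
    names(eff) <- genes
    res$effects <- eff
  }
  if (!is.null(direction_column)) {
    dir <- trimws(tab[[direction_column]])
    names(dir) <- genes
    res$direction <- dir
  }
  res
}

#' Construct a screen result from a named measure vector
#'
#' @param screen_id screen identifier.
#' @param measure_name label for the significance measure.
#' @param measures named numeric vector: one entry per tested gene, values in
#'   \[0,1\] or `NA` for tested-but-unmeasured genes. Names are harmonized.
#' @param effects optional named numeric effect sizes (tie-breaking only).
#' @param direction optional named character direction labels.
#' @return a `screen_result` object.
#' @export
new_screen_result <- function(screen_id, measure_name = "p", measures,
                              effects = NULL, direction = NULL) {
  stopifnot(is.numeric(measures), !is.null(names(measures)))
  names(measures) <- harmonize_symbol(names(measures))
  ok <- is.na(measures) | (measures >= 0 & measures <= 1)
  if (!all(ok)) {
    stop("significance values outside [0,1] for: ",
         paste(names(measures)[!ok], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(measures))) {
    stop("duplicate genes in screen '", screen_id, "'", call. = FALSE)
  }
  structure(list(screen_id = as.character(screen_id),
                 measure_name = measure_name,
                 measures = measures,
                 tested = names(measures),
                 effects = effects,
                 direction = direction),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result '", x$screen_id, "': ", length(x$tested),
      " genes tested, ", sum(!is.na(x$measures)), " with a ",
      x$measure_name, " value\n", sep = "")
  invisible(x)
}

#' Check screen genes against a gene space
#'
#' Reports (without dropping) genes tested by a screen that are absent from
#' the underlying gene space. Aggregation later excludes such genes from its
#' output; this helper makes the discrepancy visible up front.
#'
#' @param screen a `screen_result`.
#' @param space a `gene_space`.
#' @return character vector of tested genes not in the space (possibly
#'   empty), invisibly; a message reports the count when non-zero.
#' @export
check_screen_in_space <- function(screen, space) {
  stray <- setdiff(screen$tested, space)
  if (length(stray)) {
    message("screen '", screen$screen_id, "': ", length(stray),
            " tested gene(s) absent from the gene space")
  }
  invisible(stray)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard GMT dialect: one gene set per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Member symbols are
#' harmonized and de-duplicated (duplicates within a line warn).
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: named list of character vectors (term_id
#'   to members) with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    ids[i] <- fields[1L]
    desc[i] <- fields[2L]
    members <- harmonize_symbol(fields[-(1:2)])
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", ids[i],
              "'): duplicated member(s) removed", call. = FALSE)
      members <- unique(members)
    }
    sets[[i]] <- members
  }
  names(sets) <- ids
  new_gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term_id -> member genes);
#'   members are harmonized, must be non-empty.
#' @param descriptions optional character vector of term descriptions
#'   parallel to `sets` (defaults to the term ids).
#' @return a `gene_set_collection` object.
#' @export
new_gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) {
    stop("gene sets must be non-empty: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(harmonize_symbol(g)))
  if (is.null(descriptions)) descriptions <- names(sets)
  stopifnot(length(descriptions) == length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets, sizes",
      min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` preserves sets,
#' member order and descriptions for harmonized collections.
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
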