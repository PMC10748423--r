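#' Hypergeometric overrepresentation analysis
#'
#' Tests each term of a gene-set collection for overrepresentation in a
#' candidate list against a background universe. For a term with
#' `term_size` members in a background of `background_size` genes and a
#' candidate list of `candidate_size` genes, the one-sided upper-tail
#' p-value is `P(X >= overlap)` with
#' `X ~ Hypergeom(background_size, term_size, candidate_size)`.
#' P-values are Benjamini-Hochberg adjusted across the tested terms.
#'
#' By default the background is restricted to genes annotated in at least
#' one term of the collection (common ORA practice); set
#' `use_full_space = TRUE` to use the whole supplied space instead.
#' Candidates outside the background are dropped with a warning; terms are
#' intersected with the background, and terms left empty are skipped.
#'
#' @param candidates character vector of candidate genes (harmonized).
#' @param collection a `gene_set_collection`.
#' @param background a `gene_space` (or character vector) giving the
#'   universe.
#' @param use_full_space use the whole space as background rather than its
#'   annotated subset.
#' @return data frame with one row per tested term: `term_id`, `term_name`,
#'   `term_size`, `candidate_size`, `background_size`, `overlap_count`,
#'   `p_value`, `adjusted_p`, sorted by adjusted then nominal p.
#' @export
hypergeometric_enrichment <- function(candidates, collection, background,
                                      use_full_space = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(harmonize_symbol(as.character(background)))
  if (!length(background)) stop("empty background", call. = FALSE)
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  candidates <- unique(harmonize_symbol(candidates))

  if (!use_full_space) {
    annotated <- unique(unlist(collection, use.names = FALSE))
    background <- intersect(background, annotated)
    if (!length(background)) {
      stop("no background gene is annotated in the collection",
           call. = FALSE)
    }
  }
  dropped <- setdiff(candidates, background)
  if (length(dropped)) {
    warning(length(dropped),
            " candidate(s) outside the background dropped", call. = FALSE)
    candidates <- intersect(candidates, background)
  }
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)

  B <- length(background)
  n <- length(candidates)
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    q <- length(intersect(candidates, members))
    p <- stats::phyper(q - 1, K, B - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(desc[[id]]),
               term_size = K, candidate_size = n, background_size = B,
               overlap_count = q, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop("no term intersects the background", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$adjusted_p, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition candidates into known and novel targets
#'
#' Splits a candidate list against a list of genes already under
#' therapeutic development: `known` are candidates present in the target
#' list, `novel` the remainder. The two parts always partition the input
#' (`length(known) + length(novel) == length(unique(candidates))`).
#'
#' @param candidates character vector of candidate genes (harmonized).
#' @param known_targets character vector of known therapeutic-target genes.
#' @return list with character vectors `known` and `novel`, each preserving
#'   candidate order.
#' @export
annotate_novelty <- function(candidates, known_targets) {
  candidates <- unique(as.character(candidates))
  known_targets <- unique(as.character(known_targets))
  is_known <- candidates %in% known_targets
  list(known = candidates[is_known], novel = candidates[!is_known])
}
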