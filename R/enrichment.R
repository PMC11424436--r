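#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query symbols against
#' a background universe, with the upper-tail hypergeometric probability
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (`N` universe size, `K`
#' set size in the universe, `n` query size in the universe, `k` overlap).
#' Query symbols outside the universe are dropped with a warning. The
#' recommended universe for a screened mediator panel is the panel itself,
#' not the genome.
#'
#' @param query Character vector of query symbols (e.g. mediator proteins).
#' @param sets Gene sets from [read_gmt()] (or a named list of character
#'   vectors).
#' @param universe Character vector of background symbols.
#' @param adjust Multiple-testing correction: `"BH"` (default),
#'   `"bonferroni"`, or `"none"`.
#' @return Data frame sorted by p-value: `set_id`, `description`, `k`, `K`,
#'   `n`, `N`, `pvalue`, `adjusted_p`, `overlap`.
#' @export
hypergeom_enrich <- function(query, sets, universe, adjust = "BH") {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query symbol(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  if (is.list(sets) && length(sets) > 0 && is.list(sets[[1]]) &&
      !is.null(sets[[1]]$members)) {
    members <- lapply(sets, `[[`, "members")
    descs <- vapply(sets, `[[`, character(1), "description")
    ids <- vapply(sets, `[[`, character(1), "set_id")
  } else {
    members <- sets
    ids <- names(sets)
    descs <- rep("", length(sets))
  }
  rows <- lapply(seq_along(members), function(i) {
    in_univ <- intersect(members[[i]], universe)
    K <- length(in_univ)
    hit <- intersect(query, in_univ)
    k <- length(hit)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = ids[[i]], description = descs[[i]],
               k = k, K = K, n = n, N = N, pvalue = min(p, 1),
               overlap = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  method <- switch(adjust, BH = "BH", bonferroni = "bonferroni",
                   none = "none", stop("unknown adjustment: ", adjust))
  out$adjusted_p <- stats::p.adjust(out$pvalue, method = method)
  out <- out[order(out$pvalue, out$set_id), ]
  rownames(out) <- NULL
  out[c("set_id", "description", "k", "K", "n", "N", "pvalue",
        "adjusted_p", "overlap")]
}
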