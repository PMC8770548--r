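#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then member genes.
#' Duplicate genes within a set are deduplicated; trailing empty fields are
#' ignored; duplicate set names and lines with fewer than 3 fields are
#' errors.
#'
#' @param path File path.
#' @return Named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[!(seq_along(fields) > 2 & !nzchar(fields))]
    if (length(fields) < 3) {
      stop_arg("GMT line ", i, " has fewer than 3 fields")
    }
    name <- fields[1]
    if (name %in% names(sets)) stop_arg("duplicate set name: ", name)
    genes <- unique(fields[-(1:2)])
    attr(genes, "description") <- fields[2]
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Preranked gene set enrichment analysis
#'
#' Classical running-sum enrichment: genes are ordered by decreasing score;
#' hitting an in-set gene advances the sum by its `|score|^weight` share,
#' missing one retreats uniformly; the enrichment score (ES) is the running
#' sum's maximum deviation from zero. Significance by gene-label
#' permutation: set membership is reassigned at random `n_perm` times; the
#' normalized ES (NES) divides by the mean |null ES| of matching sign, the
#' p-value is the +1-smoothed fraction of same-sign null ES at least as
#' extreme, and q is the BH adjustment across sets.
#'
#' @param ranked_scores Named numeric vector: per-gene ranking metric (e.g.
#'   correlation with the ICI score), names = unique gene ids.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param weight Exponent on `|score|` for in-set increments; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic.
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed.
#' @param min_size Minimum in-ranking set size.
#' @return data.frame with `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
gsea_preranked <- function(ranked_scores, sets, weight = 1, n_perm = 1000,
                           seed = 1, min_size = 5) {
  if (is.null(names(ranked_scores))) stop_arg("ranking scores must be named")
  if (anyDuplicated(names(ranked_scores))) stop_arg("duplicate gene ids in ranking")
  if (any(!is.finite(ranked_scores))) stop_arg("ranking scores must be finite")
  ord <- order(ranked_scores, decreasing = TRUE)
  scores <- ranked_scores[ord]
  genes <- names(scores)
  n <- length(genes)

  sizes <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes < n
  if (!any(keep)) {
    warning("no gene set passes the size filter", call. = FALSE)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric()))
  }
  sets <- sets[keep]
  sizes <- sizes[keep]

  es_stat <- function(in_set) {
    w <- abs(scores)^weight
    w_in <- sum(w[in_set])
    inc <- ifelse(in_set, if (w_in > 0) w / w_in else 1 / sum(in_set),
                  -1 / (n - sum(in_set)))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }

  es <- vapply(names(sets), function(nm) {
    es_stat(genes %in% sets[[nm]])
  }, numeric(1))

  null_es <- with_seed(seed, {
    lapply(sizes, function(m) {
      vapply(seq_len(n_perm), function(i) {
        in_set <- logical(n)
        in_set[sample.int(n, m)] <- TRUE
        es_stat(in_set)
      }, numeric(1))
    })
  })

  p <- nes <- numeric(length(es))
  for (i in seq_along(es)) {
    same_sign <- null_es[[i]][sign(null_es[[i]]) == sign(es[i])]
    if (length(same_sign) == 0) {
      nes[i] <- NA_real_
      p[i] <- 1 / (1 + n_perm)
    } else {
      nes[i] <- es[i] / mean(abs(same_sign))
      p[i] <- (1 + sum(abs(same_sign) >= abs(es[i]))) /
        (1 + length(same_sign))
    }
  }
  data.frame(
    set = names(sets), size = unname(sizes), es = unname(es),
    nes = nes, p = p, q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p for the overlap between a query gene list and
#' each set, within a stated universe; BH adjustment across sets.
#'
#' @param query Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all assayed genes.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
ora_hypergeometric <- function(query, universe, sets) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop_arg("empty query gene list")
  if (!all(query %in% universe)) {
    stop_arg("query genes outside the universe: ",
             paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    k <- length(intersect(set, query))
    # P(X >= k), X ~ Hypergeometric(white = |set|, black = N - |set|, drawn = |query|)
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
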