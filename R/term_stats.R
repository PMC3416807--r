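corpus_col <- function(corpus, name, what = "term") {
  if (!name %in% names(corpus))
    abort(sprintf("%s \"%s\" is not a column of the corpus", what, name))
  v <- corpus[[name]]
  if (!all(v %in% c(0, 1)))
    abort(sprintf("%s column \"%s\" is not binary 0/1", what, name))
  v == 1
}

#' Jaccard association between two literature terms
#'
#' Over the sets of studies carrying each term: `J = |A n B| / |A u B|`,
#' the size of the intersection divided by the size of the union, reported
#' together with its natural logarithm (the scale on which phenotype maps
#' are thresholded). Disjoint sets give `J = 0` and `ln_jaccard = -Inf`.
#'
#' @param corpus Study corpus tibble with binary 0/1 term columns.
#' @param term_a,term_b Term column names.
#' @return A one-row tibble: `term_a`, `term_b`, `n_a`, `n_b`,
#'   `n_intersect`, `n_union`, `jaccard`, `ln_jaccard`.
#' @export
jaccard_association <- function(corpus, term_a, term_b) {
  a <- corpus_col(corpus, term_a)
  b <- corpus_col(corpus, term_b)
  ni <- sum(a & b); nu <- sum(a | b)
  j <- if (nu == 0) 0 else ni / nu
  tibble(term_a = term_a, term_b = term_b,
         n_a = sum(a), n_b = sum(b), n_intersect = ni, n_union = nu,
         jaccard = j, ln_jaccard = if (j > 0) log(j) else -Inf)
}

#' Phenotype map: thresholded term co-occurrence structure
#'
#' All pairwise Jaccard associations between the given terms, thresholded on
#' the natural-log scale: the edge list keeps pairs with
#' `ln_jaccard > threshold_ln_j` (default -10, keeping only the strongest
#' associations). Per-term association percentages give each term's share
#' of its summed Jaccard association over the retained edges.
#'
#' @param corpus Study corpus tibble.
#' @param terms Character vector of term columns; defaults to the corpus's
#'   `terms` attribute.
#' @param threshold_ln_j Threshold on `ln(J)`; edges must exceed it.
#' @return A list of class `phenotype_map`: `ln_j` (symmetric labeled
#'   matrix), `edges` (tibble of retained pairs), `shares` (tibble of
#'   per-term association percentages).
#' @export
phenotype_map <- function(corpus, terms = NULL, threshold_ln_j = -10) {
  terms <- terms %||% attr(corpus, "terms")
  if (is.null(terms) || length(terms) < 2)
    abort("need at least two terms")
  pairs <- utils::combn(terms, 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(i)
    jaccard_association(corpus, pairs[1, i], pairs[2, i]))
  ln_j <- matrix(0, length(terms), length(terms),
                 dimnames = list(terms, terms))
  for (i in seq_len(nrow(edges))) {
    ln_j[edges$term_a[i], edges$term_b[i]] <- edges$ln_jaccard[i]
    ln_j[edges$term_b[i], edges$term_a[i]] <- edges$ln_jaccard[i]
  }
  kept <- edges %>% filter(.data$ln_jaccard > threshold_ln_j)
  shares <- tibble(term = terms) %>%
    mutate(association = vapply(.data$term, function(tm)
      sum(kept$jaccard[kept$term_a == tm | kept$term_b == tm]),
      numeric(1))) %>%
    mutate(percent = if (sum(.data$association) > 0)
      100 * .data$association / sum(.data$association) else 0)
  structure(list(ln_j = ln_j, edges = kept, shares = shares,
                 threshold_ln_j = threshold_ln_j),
            class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat(sprintf("<phenotype_map> %d terms, %d associations above ln(J) > %g\n",
              nrow(x$ln_j), nrow(x$edges), x$threshold_ln_j))
  invisible(x)
}

#' @method tidy phenotype_map
#' @export
tidy.phenotype_map <- function(x, ...) x$edges

#' Forward inference: P(activation | term)
#'
#' For each region, the fraction of the studies carrying the term that
#' report activation there.
#'
#' @param corpus Study corpus tibble with binary term and region columns.
#' @param term Term column name.
#' @param regions Region column names; defaults to the corpus's `regions`
#'   attribute.
#' @return A tibble with `region`, `n_term`, `n_act_term`,
#'   `p_act_given_term`.
#' @export
forward_inference <- function(corpus, term, regions = NULL) {
  regions <- regions %||% attr(corpus, "regions")
  if (is.null(regions)) abort("no regions given")
  t_in <- corpus_col(corpus, term)
  if (!any(t_in)) abort(sprintf("term \"%s\" occurs in no study", term))
  purrr::map_dfr(regions, function(rg) {
    a <- corpus_col(corpus, rg, "region")
    tibble(region = rg, n_term = sum(t_in), n_act_term = sum(a & t_in),
           p_act_given_term = sum(a & t_in) / sum(t_in))
  })
}

#' Reverse inference: P(term | activation)
#'
#' Bayes' rule per region:
#' `P(term | act) = P(act | term) P(term) /
#'  (P(act | term) P(term) + P(act | !term) (1 - P(term)))`.
#' The prior `P(term)` is the empirical base rate of the term in the corpus
#' by default, or a user-supplied value (0.5 mimics a uniform prior).
#' Regions where activation never occurs under either likelihood get an
#' `NA` posterior (undefined, not 0).
#'
#' @inheritParams forward_inference
#' @param prior `"empirical"` or a probability in (0, 1).
#' @return A tibble with `region`, `p_act_given_term`,
#'   `p_act_given_notterm`, `prior`, `p_term_given_act`.
#' @export
reverse_inference <- function(corpus, term, regions = NULL,
                              prior = "empirical") {
  regions <- regions %||% attr(corpus, "regions")
  if (is.null(regions)) abort("no regions given")
  t_in <- corpus_col(corpus, term)
  if (!any(t_in)) abort(sprintf("term \"%s\" occurs in no study", term))
  p_t <- if (identical(prior, "empirical")) mean(t_in) else {
    if (!is.numeric(prior) || prior <= 0 || prior >= 1)
      abort("`prior` must be \"empirical\" or a probability in (0, 1)")
    prior
  }
  purrr::map_dfr(regions, function(rg) {
    a <- corpus_col(corpus, rg, "region")
    p_a_t <- sum(a & t_in) / sum(t_in)
    p_a_nt <- if (any(!t_in)) sum(a & !t_in) / sum(!t_in) else 0
    denom <- p_a_t * p_t + p_a_nt * (1 - p_t)
    tibble(region = rg, p_act_given_term = p_a_t,
           p_act_given_notterm = p_a_nt, prior = p_t,
           p_term_given_act = if (denom > 0) p_a_t * p_t / denom
           else NA_real_)
  })
}

#' Spatial agreement between a reverse-inference map and a conjunction map
#'
#' Thresholds the reverse-inference probability map at `threshold` and
#' compares the resulting binary region with the conjunction map via the
#' Dice coefficient.
#'
#' @param reverse_map A `volume_map` of `P(term | activation)` values.
#' @param conjunction_map A binary `volume_map` on the same grid.
#' @param threshold Probability cut applied to `reverse_map` (default 0.5).
#' @return A one-row tibble: `threshold`, `dice`, `n_reverse`,
#'   `n_conjunction`, `n_intersect`.
#' @export
specificity_overlap <- function(reverse_map, conjunction_map,
                                threshold = 0.5) {
  stop_if_grid_mismatch(list(reverse_map, conjunction_map))
  b <- volume_map(array(as.numeric(reverse_map$values > threshold),
                        dim(reverse_map$values)),
                  reverse_map$voxel_size, reverse_map$origin,
                  reverse_map$mask)
  d <- dice_coefficient(b, conjunction_map)
  tibble(threshold = threshold, dice = d$dice, n_reverse = d$n_a,
         n_conjunction = d$n_b, n_intersect = d$n_intersect)
}
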