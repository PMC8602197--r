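# broom-style accessors for the fitted result objects

#' Tidy a differential-expression result
#'
#' @param x A `circ_de` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per tested feature.
#' @export
tidy.circ_de <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "circ_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x A `circ_de` tibble.
#' @param ... Unused.
#' @return Tibble: `tissue_a`, `tissue_b`, `n_tested`, `n_up`, `n_down`,
#'   `n_de`.
#' @export
glance.circ_de <- function(x, ...) {
  pair <- attr(x, "pair")
  tibble(tissue_a = pair[1], tissue_b = pair[2], n_tested = nrow(x),
         n_up = sum(x$status == "up"), n_down = sum(x$status == "down"),
         n_de = sum(x$status != "ns"))
}

#' Tidy a Z-score clustering
#'
#' @param x A `circ_cluster`.
#' @param ... Unused.
#' @return Tibble: `feature_id`, `cluster`.
#' @export
tidy.circ_cluster <- function(x, ...) x$assignments

#' One-row summary of a Z-score clustering
#'
#' @param x A `circ_cluster`.
#' @param ... Unused.
#' @return Tibble: `k`, `n_features`, `n_profiles`, `n_dropped`.
#' @export
glance.circ_cluster <- function(x, ...) {
  tibble(k = x$k, n_features = nrow(x$z), n_profiles = ncol(x$z),
         n_dropped = length(x$dropped))
}

#' Tidy a circRNA catalog
#'
#' @param x A `circ_catalog`.
#' @param ... Unused.
#' @return The junction table with per-sample counts joined long.
#' @export
tidy.circ_catalog <- function(x, ...) {
  x$junctions %>% left_join(x$counts, by = "circ_id")
}

#' One-row summary of a circRNA catalog
#'
#' @param x A `circ_catalog`.
#' @param ... Unused.
#' @return Tibble: `n_junctions`, `n_samples`, `total_junction_reads`.
#' @export
glance.circ_catalog <- function(x, ...) {
  tibble(n_junctions = nrow(x$junctions), n_samples = length(x$samples),
         total_junction_reads = sum(x$counts$n_reads))
}
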