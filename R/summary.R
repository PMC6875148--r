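#' Exact binomial sign test
#'
#' Tests whether the proportion of negative values among `n_total` exceeds
#' chance (one-sided) or differs from it (two-sided), with success
#' probability 0.5 under the null. One-sided: `P(X >= n_negative)`;
#' two-sided: `min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param n_negative count of negative values, `0 <= n_negative <= n_total`.
#' @param n_total number of values (>= 1).
#' @param alternative `"one_sided_negative"` or `"two_sided"`.
#' @return the p value.
#' @export
sign_test <- function(n_negative, n_total,
                      alternative = c("one_sided_negative", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_total >= 1, n_negative >= 0, n_negative <= n_total)
  upper <- pbinom(n_negative - 1, n_total, 0.5, lower.tail = FALSE)
  if (alternative == "one_sided_negative") return(upper)
  lower <- pbinom(n_negative, n_total, 0.5)
  min(1, 2 * min(lower, upper))
}

#' Ratio of two network volumes
#'
#' @param volume_a,volume_b volumes in mm^3.
#' @return `volume_a / volume_b`.
#' @export
volume_ratio <- function(volume_a, volume_b) {
  stopifnot(volume_a > 0, volume_b > 0)
  volume_a / volume_b
}

# region_id "L12"/"R12" -> pair_id + side
parse_region_id <- function(ids) {
  side <- ifelse(substr(ids, 1, 1) == "L", "left", "right")
  pair <- as.integer(substring(ids, 2))
  if (anyNA(pair)) stop("region ids must look like 'L<pair_id>'/'R<pair_id>'")
  data.frame(region_id = ids, pair_id = pair, hemisphere = side)
}

#' Summarize networks: membership, volume, inter-network correlation
#'
#' Per network: member regions and total volume (sum of the selected-side
#' region volumes). Per network pair: the mean inter-network correlation R
#' (mean over subjects of each subject's mean correlation across all
#' between-network region pairs), the fraction of subjects whose mean is
#' negative, the one-sided sign-test p value of that fraction and its
#' Bonferroni adjustment over the number of network pairs, and the volume
#' ratio (larger over smaller).
#'
#' @param partition a `network_partition`.
#' @param cstack a `connectivity_stack` over the same regions.
#' @param atlas a `homotopic_atlas` providing region geometry.
#' @param regions optional region table (`region_id`, `pair_id`,
#'   `hemisphere`); parsed from region ids if omitted.
#' @return object of class `network_summary`: list with `networks`
#'   (data.frame: network, n_regions, members, volume_mm3) and
#'   `network_pairs` (data.frame: network_a, network_b, mean_R,
#'   fraction_negative, sign_p, sign_p_bonferroni, volume_ratio).
#' @export
network_summary <- function(partition, cstack, atlas, regions = NULL) {
  stopifnot(inherits(partition, "network_partition"),
            inherits(cstack, "connectivity_stack"))
  asg <- partition$assignment
  ids <- names(asg)
  stopifnot(all(ids %in% dimnames(cstack$cor)[[1]]))
  if (is.null(regions)) regions <- cstack$regions
  if (is.null(regions)) regions <- parse_region_id(ids)
  if (is.null(regions$region_id)) regions <- as_region_table(regions)
  regions <- regions[match(ids, regions$region_id), ]
  nets <- sort(unique(asg))
  vols <- vapply(nets, function(k) {
    m <- ids[asg == k]
    i <- match(m, regions$region_id)
    sum(vapply(seq_along(i), function(j)
      region_volume(atlas, regions$pair_id[i[j]], regions$hemisphere[i[j]]), 0))
  }, 0)
  networks <- data.frame(
    network = nets,
    n_regions = as.integer(table(asg)[as.character(nets)]),
    members = vapply(nets, function(k)
      paste(sort(ids[asg == k]), collapse = ", "), ""),
    volume_mm3 = vols)
  n_s <- dim(cstack$cor)[3]
  combs <- if (length(nets) >= 2) utils::combn(nets, 2) else
    matrix(integer(), 2, 0)
  pair_rows <- lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    ia <- which(asg == a); ib <- which(asg == b)
    subj_means <- vapply(seq_len(n_s), function(s)
      mean(cstack$cor[ia, ib, s]), 0)
    n_neg <- sum(subj_means < 0)
    data.frame(network_a = a, network_b = b,
               mean_R = mean(subj_means),
               fraction_negative = n_neg / n_s,
               sign_p = sign_test(n_neg, n_s, "one_sided_negative"),
               volume_ratio = max(vols[c(a, b)]) / min(vols[c(a, b)]))
  })
  network_pairs <- do.call(rbind, pair_rows)
  if (!is.null(network_pairs) && nrow(network_pairs)) {
    network_pairs$sign_p_bonferroni <-
      pmin(1, network_pairs$sign_p * nrow(network_pairs))
    network_pairs <- network_pairs[, c("network_a", "network_b", "mean_R",
                                       "fraction_negative", "sign_p",
                                       "sign_p_bonferroni", "volume_ratio")]
  }
  structure(list(networks = networks, network_pairs = network_pairs),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Networks:\n")
  print(x$networks[, c("network", "n_regions", "volume_mm3")],
        row.names = FALSE)
  if (!is.null(x$network_pairs) && nrow(x$network_pairs)) {
    cat("Inter-network correlations:\n")
    print(x$network_pairs, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
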