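#' Mahalanobis placement of individuals relative to the parent species
#'
#' Computes, for every individual, the squared Mahalanobis distances from its
#' mean feature vector to the two parental centroids, using the pooled
#' within-group covariance of the parent species' calls. One point per animal:
#' each individual's feature vector is the mean over its calls. The resulting
#' (D² to parent A, D² to parent B) pairs are the coordinates of the
#' intermediacy scatter.
#'
#' @param measurements data.frame of call-level measurements with a group
#'   column, an individual column and the feature columns. All groups present
#'   are placed; the covariance and centroids come from the parent groups
#'   only.
#' @param features feature column names (default duration, 50% quartile,
#'   entropy).
#' @param parents the two parent group labels (default `tien_shan`, `bank`).
#' @param group,individual column names.
#' @return object of class `mahalanobis_placement`: data.frame with one row
#'   per individual (`individual`, `group`, `n_calls`, `d2_<parentA>`,
#'   `d2_<parentB>`), with the parent labels, centroids and pooled covariance
#'   as attributes.
#' @export
mahalanobis_placement <- function(measurements,
                                  features = c("duration_s", "q50_hz",
                                               "entropy"),
                                  parents = c("tien_shan", "bank"),
                                  group = "group",
                                  individual = "individual") {
  if (length(parents) != 2L) stop_volecall("exactly two parent groups")
  miss <- setdiff(c(features, group, individual), names(measurements))
  if (length(miss) > 0)
    stop_volecall("measurements lack column(s): ", paste(miss, collapse = ", "))
  g <- as.character(measurements[[group]])
  if (!all(parents %in% g))
    stop_volecall("parent group(s) absent from the data")
  x <- as.matrix(measurements[features])
  if (anyNA(x)) stop_volecall("missing values in the feature set")
  pfit <- dfa(x[g %in% parents, , drop = FALSE],
              factor(g[g %in% parents], levels = parents))
  S <- pfit$cov
  mu <- pfit$means
  ind <- interaction(g, measurements[[individual]], drop = TRUE, sep = "/")
  rows <- lapply(levels(ind), function(l) {
    sel <- ind == l
    xm <- colMeans(x[sel, , drop = FALSE])
    data.frame(individual = as.character(
                 measurements[[individual]][sel][1]),
               group = g[sel][1], n_calls = sum(sel),
               d2_a = stats::mahalanobis(rbind(xm), mu[1, ], S),
               d2_b = stats::mahalanobis(rbind(xm), mu[2, ], S),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- paste0("d2_", parents)
  attr(out, "parents") <- parents
  attr(out, "features") <- features
  attr(out, "centroids") <- mu
  attr(out, "pooled_cov") <- S
  class(out) <- c("mahalanobis_placement", "data.frame")
  out
}

#' @export
print.mahalanobis_placement <- function(x, ...) {
  cat("Squared Mahalanobis distances to the parental centroids\n")
  cat("features:", paste(attr(x, "features"), collapse = ", "), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Intermediacy scatter of individuals in parental Mahalanobis coordinates
#'
#' Plots each individual at (D² to parent A, D² to parent B); parents cluster
#' near their own axis, intermediate hybrids fall between the parental
#' scatters, off both.
#'
#' @param x a [mahalanobis_placement].
#' @param ... passed to [graphics::plot()].
#' @export
plot.mahalanobis_placement <- function(x, ...) {
  parents <- attr(x, "parents")
  d2a <- x[[paste0("d2_", parents[1])]]
  d2b <- x[[paste0("d2_", parents[2])]]
  grp <- factor(x$group, levels = unique(c(parents, x$group)))
  graphics::plot(d2a, d2b, pch = as.integer(grp), col = as.integer(grp),
                 xlab = bquote(D^2 ~ "to" ~ .(parents[1])),
                 ylab = bquote(D^2 ~ "to" ~ .(parents[2])), ...)
  graphics::legend("topright", legend = levels(grp),
                   pch = seq_len(nlevels(grp)), col = seq_len(nlevels(grp)))
  invisible(x)
}

#' Summarize hybrid intermediacy from a Mahalanobis placement
#'
#' For every non-parent individual: which parent it lies nearer to (smaller
#' D², with ties reported as `"tie"`), and whether it is intermediate — for
#' both parents, its D² to that parent exceeds the largest self-distance of
#' that parent's own individuals while staying below the smallest distance of
#' the opposite parent's individuals (i.e. it falls in the gap between the two
#' parental scatters along both axes).
#'
#' @param pl a [mahalanobis_placement].
#' @param tol relative tolerance for calling a tie (default 1e-9).
#' @return list with `per_individual` (data.frame: individual, group, the two
#'   D², `nearer`, `intermediate`), `counts` (table of `nearer`) and
#'   `majority_nearer` (label, or `"tie"`).
#' @export
intermediacy_summary <- function(pl, tol = 1e-9) {
  parents <- attr(pl, "parents")
  da <- pl[[paste0("d2_", parents[1])]]
  db <- pl[[paste0("d2_", parents[2])]]
  is_a <- pl$group == parents[1]
  is_b <- pl$group == parents[2]
  hyb <- !(is_a | is_b)
  if (!any(hyb)) stop_volecall("no non-parent individuals to summarize")
  # parental scatter bounds along each axis
  self_a_hi <- max(da[is_a]); cross_a_lo <- min(da[is_b])
  self_b_hi <- max(db[is_b]); cross_b_lo <- min(db[is_a])
  nearer <- ifelse(abs(da - db) <= tol * pmax(da + db, 1), "tie",
                   ifelse(da < db, parents[1], parents[2]))
  intermediate <- da > self_a_hi & da < cross_a_lo &
    db > self_b_hi & db < cross_b_lo
  per <- data.frame(pl[c("individual", "group")],
                    d2_a = da, d2_b = db,
                    nearer = nearer, intermediate = intermediate,
                    stringsAsFactors = FALSE)[hyb, ]
  names(per)[3:4] <- paste0("d2_", parents)
  rownames(per) <- NULL
  counts <- table(factor(per$nearer, levels = c(parents, "tie")))
  top <- names(counts)[counts == max(counts)]
  list(per_individual = per, counts = counts,
       majority_nearer = if (length(top) == 1L) top else "tie",
       n_intermediate = sum(per$intermediate))
}
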