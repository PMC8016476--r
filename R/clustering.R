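# ---- internal clustering validity indices --------------------------------
#
# Each index is computed from the profile matrix x, the pairwise distance
# matrix (where needed) and a list of cutree assignments per k. Indices are
# implemented from their published formulas; each carries its own optimal-k
# selection rule (max, min, elbow, or the gap/Hartigan rules).

cluster_wss <- function(x, ct) {
  sum(vapply(unique(ct), function(g) {
    xg <- x[ct == g, , drop = FALSE]
    sum(sweep(xg, 2, colMeans(xg))^2)
  }, numeric(1)))
}

index_calinski_harabasz <- function(x, ct) {
  n <- nrow(x)
  k <- length(unique(ct))
  gm <- colMeans(x)
  w <- cluster_wss(x, ct)
  b <- sum(vapply(unique(ct), function(g) {
    xg <- x[ct == g, , drop = FALSE]
    nrow(xg) * sum((colMeans(xg) - gm)^2)
  }, numeric(1)))
  (b / (k - 1)) / (w / (n - k))
}

# mean silhouette width, computed via cluster-wise mean distances
index_silhouette <- function(dm, ct) {
  ks <- sort(unique(ct))
  sizes <- table(ct)[as.character(ks)]
  ind <- vapply(ks, function(g) as.numeric(ct == g), numeric(length(ct)))
  sums <- dm %*% ind                       # point x cluster distance sums
  means <- sweep(sums, 2, as.numeric(sizes), `/`)
  own <- match(ct, ks)
  a <- vapply(seq_along(ct), function(i) {
    sz <- sizes[[own[i]]]
    if (sz == 1L) return(0)
    sums[i, own[i]] / (sz - 1L)
  }, numeric(1))
  b <- vapply(seq_along(ct), function(i) {
    min(means[i, -own[i]])
  }, numeric(1))
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1L] <- 0
  mean(s)
}

index_davies_bouldin <- function(x, ct) {
  ks <- sort(unique(ct))
  cent <- t(vapply(ks, function(g) colMeans(x[ct == g, , drop = FALSE]),
                   numeric(ncol(x))))
  disp <- vapply(seq_along(ks), function(i) {
    xg <- x[ct == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2, cent[i, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(cent))
  mean(vapply(seq_along(ks), function(i) {
    max((disp[i] + disp[-i]) / dmat[i, -i])
  }, numeric(1)))
}

index_dunn <- function(dm, ct) {
  ks <- sort(unique(ct))
  diam <- max(vapply(ks, function(g) {
    idx <- which(ct == g)
    if (length(idx) < 2L) return(0)
    max(dm[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j) {
      min(dm[ct == ks[i], ct == ks[j], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

index_c <- function(dvec, within_pair) {
  nw <- sum(within_pair)
  s <- sum(dvec[within_pair])
  srt <- sort(dvec)
  smin <- sum(srt[seq_len(nw)])
  smax <- sum(srt[seq.int(length(srt) - nw + 1L, length(srt))])
  (s - smin) / (smax - smin)
}

index_mcclain_rao <- function(dvec, within_pair) {
  nw <- sum(within_pair)
  nb <- length(dvec) - nw
  (sum(dvec[within_pair]) / nw) / (sum(dvec[!within_pair]) / nb)
}

# logical vector over dist entries: TRUE if the pair is within one cluster
within_pair_mask <- function(ct) {
  n <- length(ct)
  mask <- logical(n * (n - 1L) / 2L)
  pos <- 1L
  for (j in seq_len(n - 1L)) {
    len <- n - j
    mask[seq.int(pos, pos + len - 1L)] <- ct[j] == ct[seq.int(j + 1L, n)]
    pos <- pos + len
  }
  mask
}

default_cluster_indices <- function() {
  c("calinski_harabasz", "silhouette", "davies_bouldin", "dunn", "c_index",
    "ball_hall", "hartigan", "krzanowski_lai", "mcclain_rao", "gap")
}

#' Choose the number of clusters by majority vote of validity indices
#'
#' Clusters the scaled per-gene profiles with deterministic agglomerative
#' hierarchical clustering (Ward linkage, Euclidean distance), evaluates a
#' set of internal validity indices over a range of k, lets each index vote
#' for its optimal k by its own published selection rule, and picks the
#' majority (ties broken toward the smaller k, for parsimony).
#'
#' Index set (each implemented from its formula): Calinski-Harabasz (max),
#' mean silhouette width (max), Davies-Bouldin (min), Dunn (max), C-index
#' (min), Ball-Hall (largest drop of within-cluster dispersion per cluster),
#' Hartigan (smallest k with H(k) <= 10), Krzanowski-Lai (max), McClain-Rao
#' (min), and the gap statistic (uniform reference distribution over the
#' feature ranges, first k whose gap exceeds gap(k+1) minus its standard
#' error; fixed internal seed, so the whole procedure is deterministic).
#'
#' @param scaled A `ScaledMatrix` (see [scale_by_growth_intercept()] /
#'   [scale_by_reference_mean()]); profiles with missing values are dropped.
#' @param k_range Candidate numbers of clusters (default 2:8).
#' @param indices Character vector of index names, or `"all"`.
#' @param standardize `"none"` (default: the GR/NM scaling has already
#'   removed per-gene magnitude) or `"zscore"` (additionally z-score each
#'   profile).
#' @param gap_b Number of gap-statistic reference datasets (default 5).
#' @return A `ClusterResult`: list with `k` (chosen), `votes` (named integer
#'   per index), `assignments` (gene -> cluster at the chosen k, labels
#'   ordered by descending cluster size), `sizes`, `algorithm`.
#' @export
optimal_cluster_number <- function(scaled, k_range = 2:8, indices = "all",
                                   standardize = c("none", "zscore"),
                                   gap_b = 5L) {
  stopifnot(inherits(scaled, "ScaledMatrix"))
  standardize <- match.arg(standardize)
  if (identical(indices, "all")) indices <- default_cluster_indices()
  bad <- setdiff(indices, default_cluster_indices())
  if (length(bad)) {
    stop("unknown index/indices: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- prepare_profiles(scaled, standardize)
  n <- nrow(x)
  if (n < 10L) stop("need >= 10 complete gene profiles", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= n) stop("k range exceeds the gene count", call. = FALSE)

  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  # within-cluster SS for k-1 .. k+1 around the range (elbow-style rules)
  k_ext <- seq.int(max(1L, min(k_range) - 1L), min(n - 1L, max(k_range) + 1L))
  cuts <- lapply(k_ext, function(k) stats::cutree(hc, k))
  names(cuts) <- k_ext
  wss <- vapply(cuts, function(ct) cluster_wss(x, ct), numeric(1))

  dm <- NULL
  dvec <- NULL
  need_dm <- any(c("silhouette", "dunn") %in% indices)
  need_dvec <- any(c("c_index", "mcclain_rao") %in% indices)
  if (need_dm) dm <- as.matrix(d)
  if (need_dvec) dvec <- as.numeric(d)

  per_k <- function(fun) {
    vapply(as.character(k_range), function(k) fun(cuts[[k]], as.integer(k)),
           numeric(1))
  }
  votes <- integer(0)
  vote <- function(name, k) votes[[name]] <<- as.integer(k)

  for (idx in indices) {
    switch(idx,
      calinski_harabasz = {
        v <- per_k(function(ct, k) index_calinski_harabasz(x, ct))
        vote(idx, k_range[which.max(v)])
      },
      silhouette = {
        v <- per_k(function(ct, k) index_silhouette(dm, ct))
        vote(idx, k_range[which.max(v)])
      },
      davies_bouldin = {
        v <- per_k(function(ct, k) index_davies_bouldin(x, ct))
        vote(idx, k_range[which.min(v)])
      },
      dunn = {
        v <- per_k(function(ct, k) index_dunn(dm, ct))
        vote(idx, k_range[which.max(v)])
      },
      c_index = {
        v <- per_k(function(ct, k) index_c(dvec, within_pair_mask(ct)))
        vote(idx, k_range[which.min(v)])
      },
      mcclain_rao = {
        v <- per_k(function(ct, k)
          index_mcclain_rao(dvec, within_pair_mask(ct)))
        vote(idx, k_range[which.min(v)])
      },
      ball_hall = {
        # mean within-cluster dispersion per cluster; largest successive drop
        bh <- wss[as.character(k_ext)] / k_ext
        drops <- bh[match(k_range, k_ext) - 1L] - bh[match(k_range, k_ext)]
        vote(idx, k_range[which.max(drops)])
      },
      hartigan = {
        h <- vapply(k_ext, function(k) {
          w_k1 <- wss[as.character(k + 1L)]
          if (is.na(w_k1) || w_k1 <= 0) return(NA_real_)
          (wss[as.character(k)] / w_k1 - 1) * (n - k - 1)
        }, numeric(1))
        names(h) <- k_ext
        # largest drop of H between successive levels marks the knee
        drops <- h[as.character(k_range - 1L)] - h[as.character(k_range)]
        vote(idx, k_range[which.max(drops)])
      },
      krzanowski_lai = {
        p <- ncol(x)
        diff_k <- function(k) {
          (k - 1)^(2 / p) * wss[as.character(k - 1L)] -
            k^(2 / p) * wss[as.character(k)]
        }
        kl <- vapply(k_range, function(k) {
          d1 <- diff_k(k)
          d2 <- diff_k(k + 1L)
          if (is.na(d1) || is.na(d2) || abs(d2) < 1e-300) return(0)
          abs(d1 / d2)
        }, numeric(1))
        vote(idx, k_range[which.max(kl)])
      },
      gap = {
        vote(idx, gap_statistic_k(x, k_range, wss, gap_b))
      })
  }
  tab <- table(factor(votes, levels = k_range))
  chosen <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest k
  assign_chosen <- order_cluster_labels(cuts[[as.character(chosen)]])
  names(assign_chosen) <- rownames(x)
  structure(list(k = chosen, votes = votes, assignments = assign_chosen,
                 sizes = as.integer(table(assign_chosen)),
                 algorithm = "hclust/ward.D2/euclidean",
                 excluded = scaled$excluded),
            class = "ClusterResult")
}

prepare_profiles <- function(scaled, standardize) {
  x <- scaled$values[stats::complete.cases(scaled$values), , drop = FALSE]
  if (standardize == "zscore") {
    sds <- apply(x, 1L, stats::sd)
    x <- x[sds > 0, , drop = FALSE]
    x <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  }
  x
}

# Tibshirani gap statistic, uniform reference drawn in the PCA rotation of
# the data (handles elongated profile clouds). Fixed internal seed: the
# procedure is fully deterministic.
gap_statistic_k <- function(x, k_range, wss, b_ref) {
  n <- nrow(x)
  ks <- c(k_range, max(k_range) + 1L)
  log_w <- log(wss[as.character(ks)])
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = 0)
  xp <- xc %*% sv$v
  rng <- apply(xp, 2L, range)
  ref_log_w <- with_seed(20210315L, {
    vapply(seq_len(b_ref), function(b) {
      xr <- vapply(seq_len(ncol(x)), function(j) {
        stats::runif(n, rng[1L, j], rng[2L, j])
      }, numeric(n))
      xr <- xr %*% t(sv$v)
      hr <- stats::hclust(stats::dist(xr), method = "ward.D2")
      vapply(ks, function(k) log(cluster_wss(xr, stats::cutree(hr, k))),
             numeric(1))
    }, numeric(length(ks)))
  })
  gap <- rowMeans(ref_log_w) - log_w
  se <- apply(ref_log_w, 1L, stats::sd) * sqrt(1 + 1 / b_ref)
  for (i in seq_along(k_range)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) return(k_range[i])
  }
  max(k_range)
}

# relabel clusters 1..k by descending size (ties: first-seen order)
order_cluster_labels <- function(ct) {
  sizes <- table(ct)
  new_order <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[new_order]] <- seq_along(sizes)
  relabel[ct]
}

#' Cluster gene profiles at a fixed k
#'
#' Deterministic agglomerative clustering (Ward linkage, Euclidean distance)
#' of the scaled profiles, cut at `k`; cluster labels are ordered by
#' descending cluster size (label 1 = largest), mirroring the
#' `GR.cluster`/`NM.cluster` convention.
#'
#' @inheritParams optimal_cluster_number
#' @param k Number of clusters (>= 2).
#' @return A `ClusterResult`.
#' @export
cluster_genes <- function(scaled, k, standardize = c("none", "zscore")) {
  stopifnot(inherits(scaled, "ScaledMatrix"))
  standardize <- match.arg(standardize)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  x <- prepare_profiles(scaled, standardize)
  if (k >= nrow(x)) stop("k exceeds the gene count", call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  ct <- order_cluster_labels(stats::cutree(hc, k))
  names(ct) <- rownames(x)
  structure(list(k = as.integer(k), votes = NULL, assignments = ct,
                 sizes = as.integer(table(ct)),
                 algorithm = "hclust/ward.D2/euclidean",
                 excluded = scaled$excluded),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k = %d, sizes = %s\n", x$k,
              paste(x$sizes, collapse = "/")))
  if (!is.null(x$votes)) {
    cat("votes:\n")
    print(x$votes)
  }
  invisible(x)
}
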