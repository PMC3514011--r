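# Sea-surface-temperature analysis: clade-wise weighted median SST with
# bootstrap confidence intervals, and rank-based partial Mantel tests of
# clade occurrence against SST distance, corrected for spatial distance.

# canonical phylogroup labels of the shipped survey table; synthetic
# tables may use any non-empty labels (e.g. clade1, clade2)
.phylogroups <- c("arcuata", "A", "B", "new_sp", "subovoidea", "edmondsoni")

#' Load a sample-occurrence table
#'
#' Reads and validates a CSV of occurrence records: one row per
#' (site, phylogroup) with the colony count, site coordinates and the mean
#' annual SST of the locality. The package ships such a table for the
#' global *Watersipora* survey as
#' `system.file("extdata", "watersipora_table1.csv", package = "coipop")`.
#'
#' @param path CSV path with columns `region`, `site`, `latitude`,
#'   `longitude`, `sst_c`, `phylogroup`, `count`, `source`.
#' @return A validated `sample_table` data frame.
#' @export
load_sample_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region", "site", "latitude", "longitude", "sst_c",
                "phylogroup", "count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty table: ", path, call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    ok <- is.finite(r$latitude) && abs(r$latitude) <= 90 &&
      is.finite(r$longitude) && abs(r$longitude) <= 180 &&
      is.finite(r$sst_c) &&
      is.finite(r$count) && r$count >= 1 && r$count == round(r$count) &&
      is.character(r$phylogroup) && nzchar(r$phylogroup)
    if (!ok) stop("malformed row ", i, " in ", path, call. = FALSE)
  }
  tab$count <- as.integer(tab$count)
  class(tab) <- c("sample_table", "data.frame")
  tab
}

# one row per colony, carrying its site attributes
.expand_colonies <- function(tab) {
  idx <- rep(seq_len(nrow(tab)), tab$count)
  out <- tab[idx, , drop = FALSE]
  out$count <- 1L
  rownames(out) <- NULL
  out
}

# analysis units for the distance matrices
.mantel_units <- function(tab, unit = c("colony", "site")) {
  unit <- match.arg(unit)
  if (unit == "colony") {
    u <- .expand_colonies(tab)
    u$unit_id <- paste0("c", seq_len(nrow(u)))
    u
  } else {
    key <- paste(tab$site, tab$latitude, tab$longitude, tab$sst_c)
    first <- !duplicated(key)
    u <- tab[first, , drop = FALSE]
    u$unit_id <- paste0("s", seq_len(nrow(u)))
    u$.key <- key[first]
    attr(u, "row_key") <- key
    u
  }
}

#' Colony-count-weighted median SST of a phylogroup
#'
#' Each table row contributes `count` copies of its SST to the multiset
#' whose median is returned (even sizes: mean of the two middle values).
#'
#' @param tab A `sample_table`.
#' @param phylogroup Phylogroup name, e.g. `"new_sp"`.
#' @return List with `phylogroup`, `n` (colonies) and `median_sst` (deg C).
#' @export
weighted_median_sst <- function(tab, phylogroup) {
  rows <- tab[tab$phylogroup == phylogroup, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown or absent phylogroup: ", phylogroup,
                             call. = FALSE)
  values <- rep(rows$sst_c, rows$count)
  list(phylogroup = phylogroup, n = length(values),
       median_sst = stats::median(values))
}

#' Bootstrap confidence interval for a clade's median SST
#'
#' Draws `resample_size` units with replacement per replicate and reports
#' the 2.5 and 97.5 percentiles (inverse-ECDF quantiles, so endpoints are
#' attainable medians) of the replicate medians. With `unit = "colony"`
#' draws are weighted by colony count; with `unit = "site"` each table row
#' contributes one value.
#'
#' @inheritParams weighted_median_sst
#' @param resample_size Units drawn per replicate (default 20).
#' @param replicates Bootstrap replicates (default 1000, minimum 100).
#' @param unit `"colony"` (default) or `"site"`.
#' @param seed Optional integer seed.
#' @return List with `phylogroup`, `n`, `median_sst`, `ci_low`, `ci_high`,
#'   `replicates`, `unit`.
#' @export
bootstrap_median_ci <- function(tab, phylogroup, resample_size = 20,
                                replicates = 1000,
                                unit = c("colony", "site"), seed = NULL) {
  unit <- match.arg(unit)
  if (replicates < 100) {
    stop("configuration error: need >= 100 replicates", call. = FALSE)
  }
  rows <- tab[tab$phylogroup == phylogroup, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown or absent phylogroup: ", phylogroup,
                             call. = FALSE)
  pool <- if (unit == "colony") rep(rows$sst_c, rows$count) else rows$sst_c
  meds <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      stats::median(sample(pool, resample_size, replace = TRUE))
    }, 0)
  })
  ci <- stats::quantile(meds, c(0.025, 0.975), type = 1, names = FALSE)
  list(phylogroup = phylogroup, n = length(pool),
       median_sst = stats::median(pool),
       ci_low = ci[1L], ci_high = ci[2L],
       replicates = replicates, unit = unit)
}

#' Distance matrices over sampling units
#'
#' `geo_distance_matrix` is the Euclidean distance on raw decimal-degree
#' (latitude, longitude) pairs — deliberately planar, not great-circle,
#' matching how the spatial correction is defined for these tests.
#' `sst_distance_matrix` is `|sst_i - sst_j|`. `clade_indicator_matrix`
#' encodes a phylogroup as presence/absence per unit and returns the 0/1
#' indicator dissimilarity `|I_i - I_j|`.
#'
#' @param tab A `sample_table`.
#' @param unit `"colony"` (one unit per colony, rows expanded by count) or
#'   `"site"`.
#' @return A [dist_matrix()].
#' @export
geo_distance_matrix <- function(tab, unit = c("colony", "site")) {
  u <- .mantel_units(tab, unit)
  d <- as.matrix(stats::dist(cbind(u$latitude, u$longitude)))
  dist_matrix(d, labels = u$unit_id)
}

#' @rdname geo_distance_matrix
#' @export
sst_distance_matrix <- function(tab, unit = c("colony", "site")) {
  u <- .mantel_units(tab, unit)
  d <- abs(outer(u$sst_c, u$sst_c, "-"))
  dist_matrix(d, labels = u$unit_id)
}

#' @rdname geo_distance_matrix
#' @param phylogroup Phylogroup whose presence is encoded.
#' @export
clade_indicator_matrix <- function(tab, phylogroup,
                                   unit = c("colony", "site")) {
  unit <- match.arg(unit)
  u <- .mantel_units(tab, unit)
  if (unit == "colony") {
    ind <- as.numeric(u$phylogroup == phylogroup)
  } else {
    key_all <- attr(u, "row_key")
    present <- unique(key_all[tab$phylogroup == phylogroup])
    ind <- as.numeric(u$.key %in% present)
  }
  d <- abs(outer(ind, ind, "-"))
  dist_matrix(d, labels = u$unit_id)
}

# multi-clade mismatch: 0 if two units carry the same phylogroup, else 1
.clade_mismatch_matrix <- function(u) {
  d <- outer(u$phylogroup, u$phylogroup, "!=") * 1
  dist_matrix(d, labels = u$unit_id)
}

#' Partial Mantel test (rank-based by default)
#'
#' Correlates the strict lower triangles of `A` and `B` partialling out
#' `C`:
#' `r = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`.
#' With `ranked = TRUE` each triangle vector is replaced by its ranks
#' (mean rank for ties) before correlating, which linearises monotone
#' relationships. Significance comes from simultaneously permuting the rows
#' and columns of `A` and recomputing `r`, with the add-one rule.
#'
#' @param A,B,C Conformable [dist_matrix()] objects over the same units
#'   (at least 4); `A` is the matrix being tested (and permuted), `C` the
#'   nuisance (here: spatial) distance.
#' @param permutations Matrix permutations (default 10000).
#' @param ranked Rank-transform the triangle vectors first (default TRUE).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default: one-sided, positive
#'   association) or `"two.sided"`.
#' @return List with `r`, `p`, `permutations`, `ranked`, `alternative`.
#' @export
partial_mantel <- function(A, B, C, permutations = 10000, ranked = TRUE,
                           seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (!all(dim(B) == n) || !all(dim(C) == n)) {
    stop("matrices are not conformable", call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 units", call. = FALSE)
  lt <- lower.tri(A)
  idx <- which(lt, arr.ind = TRUE)
  vec <- function(M) M[lt]
  rk <- function(v) if (ranked) rank(v) else v
  a <- rk(vec(A)); b <- rk(vec(B)); c_ <- rk(vec(C))
  for (nm in c("A", "B", "C")) {
    v <- switch(nm, A = a, B = b, C = c_)
    if (stats::sd(v) == 0) {
      stop("degenerate matrix ", nm, ": zero variance in lower triangle",
           call. = FALSE)
    }
  }
  partial_r <- function(a, b, c_) {
    r_ab <- stats::cor(a, b); r_ac <- stats::cor(a, c_)
    r_bc <- stats::cor(b, c_)
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- partial_r(a, b, c_)
  # permute A's units: write ranked values back into a symmetric matrix so
  # a row/column permutation is a cheap re-indexing of the triangle
  Ar <- matrix(0, n, n)
  Ar[lt] <- a
  Ar <- Ar + t(Ar)
  m <- as.integer(permutations)
  p <- NA_real_
  if (m > 0L) {
    exceed <- with_seed(seed, {
      cnt <- 0L
      for (r in seq_len(m)) {
        prm <- sample.int(n)
        a_p <- Ar[cbind(prm[idx[, 1L]], prm[idx[, 2L]])]
        r_p <- partial_r(a_p, b, c_)
        hit <- if (alternative == "greater") r_p >= r_obs
               else abs(r_p) >= abs(r_obs)
        cnt <- cnt + as.integer(hit)
      }
      cnt
    })
    p <- (1 + exceed) / (m + 1)
  }
  list(r = r_obs, p = p, permutations = m, ranked = ranked,
       alternative = alternative)
}

#' Clade-versus-SST partial Mantel tests
#'
#' Runs the all-groups test (clade dissimilarity = 0/1 phylogroup mismatch
#' between units) and every pairwise test (presence/absence indicator
#' dissimilarity over the units of the two phylogroups), each correlated
#' with SST distance while partialling out planar geographic distance.
#'
#' @param tab A `sample_table`.
#' @param phylogroups Phylogroups to analyse (default: all present in
#'   `tab`); at least two.
#' @param permutations,ranked,unit,seed Passed to [partial_mantel()] /
#'   unit construction.
#' @return Data frame, one row per test: `test`, `group_1`, `group_2`,
#'   `n_units`, `r`, `p`, `permutations`, `ranked`, `unit`.
#' @export
clade_sst_tests <- function(tab, phylogroups = NULL, permutations = 10000,
                            ranked = TRUE, unit = c("colony", "site"),
                            seed = NULL) {
  unit <- match.arg(unit)
  if (is.null(phylogroups)) phylogroups <- sort(unique(tab$phylogroup))
  if (length(phylogroups) < 2L) {
    stop("need at least two phylogroups", call. = FALSE)
  }
  tab <- tab[tab$phylogroup %in% phylogroups, , drop = FALSE]
  rows <- list()
  run_one <- function(sub, A, label, g1, g2, test_seed) {
    B <- sst_distance_matrix(sub, unit)
    C <- geo_distance_matrix(sub, unit)
    res <- partial_mantel(A, B, C, permutations = permutations,
                          ranked = ranked, seed = test_seed)
    data.frame(test = label, group_1 = g1, group_2 = g2,
               n_units = nrow(as.matrix(A)), r = res$r, p = res$p,
               permutations = res$permutations, ranked = ranked,
               unit = unit, stringsAsFactors = FALSE)
  }
  u_all <- .mantel_units(tab, unit)
  A_all <- if (unit == "colony") .clade_mismatch_matrix(u_all) else NULL
  if (unit == "site") {
    # at site level the all-groups dissimilarity is the Jaccard-style
    # mismatch of the site's phylogroup sets
    key_all <- attr(u_all, "row_key")
    sets <- lapply(u_all$.key, function(k) {
      unique(tab$phylogroup[key_all == k])
    })
    d <- outer(seq_along(sets), seq_along(sets),
               Vectorize(function(i, j) {
                 1 - length(intersect(sets[[i]], sets[[j]])) /
                   length(union(sets[[i]], sets[[j]]))
               }))
    diag(d) <- 0
    A_all <- dist_matrix(d, labels = u_all$unit_id)
  }
  seeds <- if (is.null(seed)) rep(list(NULL), 1L + choose(length(phylogroups), 2L))
           else as.list(seed + seq_len(1L + choose(length(phylogroups), 2L)))
  k <- 1L
  rows[[k]] <- run_one(tab, A_all, "all_groups", "all", "all", seeds[[k]])
  for (i in seq_len(length(phylogroups) - 1L)) {
    for (j in seq.int(i + 1L, length(phylogroups))) {
      k <- k + 1L
      sub <- tab[tab$phylogroup %in% phylogroups[c(i, j)], , drop = FALSE]
      A <- clade_indicator_matrix(sub, phylogroups[i], unit)
      rows[[k]] <- run_one(sub, A, "pairwise", phylogroups[i],
                           phylogroups[j], seeds[[k]])
    }
  }
  do.call(rbind, rows)
}
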