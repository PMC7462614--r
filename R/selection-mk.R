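#' Default derived-allele-frequency bins for alpha(x)
#'
#' Nine equal bins spanning the polymorphic band \[0.05, 0.95\].
#' @param n_bins number of bins.
#' @param daf_min,daf_max band limits.
#' @return list with `breaks` and `mids`.
#' @export
daf_bins <- function(n_bins = 9, daf_min = 0.05, daf_max = 0.95) {
  breaks <- seq(daf_min, daf_max, length.out = n_bins + 1)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}

#' Per-gene McDonald-Kreitman tables
#'
#' Counts, per gene, fixed non-synonymous and synonymous differences
#' against the outgroup (Dn, Ds: sites with status `"fixed"`, which
#' covers both monomorphic-but-different sites and nearly fixed SNPs with
#' DAF above the fixation threshold) and polymorphic counts (Pn, Ps:
#' status `"polymorphic"`), plus frequency-binned polymorphic counts
#' Pn(x), Ps(x).
#'
#' @param polarized data.table with at least `gene_id`, `degeneracy`
#'   (`"zero_fold"`/`"four_fold"`; other classes are ignored), `daf` and
#'   `status` (as produced by [polarize()] joined with
#'   [classify_degeneracy()]).
#' @param bins a [daf_bins()] list.
#' @param genes optional character vector of all gene ids to report
#'   (genes without classified sites get zero rows).
#' @return object of class `mk_tables`: `genes` (per-gene `Dn`, `Ds`,
#'   `Pn`, `Ps`), `Pn_x`/`Ps_x` (gene x bin count matrices) and `bins`.
#' @export
mk_counts <- function(polarized, bins = daf_bins(), genes = NULL) {
  pol <- data.table::as.data.table(polarized)
  pol <- pol[degeneracy %in% c("zero_fold", "four_fold")]
  if (is.null(genes)) genes <- sort(unique(pol$gene_id))
  nb <- length(bins$mids)

  tab <- data.table::data.table(gene_id = genes, Dn = 0L, Ds = 0L,
                                Pn = 0L, Ps = 0L)
  Pn_x <- matrix(0L, nrow = length(genes), ncol = nb,
                 dimnames = list(genes, NULL))
  Ps_x <- Pn_x
  if (nrow(pol)) {
    fx <- pol[status == "fixed", .N, by = .(gene_id, degeneracy)]
    for (k in seq_len(nrow(fx))) {
      i <- match(fx$gene_id[k], genes)
      if (is.na(i)) next
      if (fx$degeneracy[k] == "zero_fold") tab$Dn[i] <- fx$N[k]
      else tab$Ds[i] <- fx$N[k]
    }
    poly <- pol[status == "polymorphic"]
    if (nrow(poly)) {
      poly[, bin := pmin(pmax(findInterval(daf, bins$breaks,
                                           rightmost.closed = TRUE), 1L), nb)]
      pc <- poly[, .N, by = .(gene_id, degeneracy, bin)]
      for (k in seq_len(nrow(pc))) {
        i <- match(pc$gene_id[k], genes)
        if (is.na(i)) next
        if (pc$degeneracy[k] == "zero_fold") Pn_x[i, pc$bin[k]] <- pc$N[k]
        else Ps_x[i, pc$bin[k]] <- pc$N[k]
      }
      tab$Pn <- as.integer(rowSums(Pn_x))
      tab$Ps <- as.integer(rowSums(Ps_x))
    }
  }
  structure(list(genes = tab, Pn_x = Pn_x, Ps_x = Ps_x, bins = bins),
            class = "mk_tables")
}

#' @export
print.mk_tables <- function(x, ...) {
  cat(sprintf("mk_tables: %d genes, %d DAF bins\n", nrow(x$genes),
              length(x$bins$mids)))
  cat(sprintf("  totals: Dn = %d, Ds = %d, Pn = %d, Ps = %d\n",
              sum(x$genes$Dn), sum(x$genes$Ds),
              sum(x$genes$Pn), sum(x$genes$Ps)))
  invisible(x)
}

#' alpha as a function of derived allele frequency
#'
#' Aggregates MK counts over genes and evaluates, per DAF bin,
#' alpha(x) = 1 - (Ds/Dn) * (Pn(x)/Ps(x)). Bins with a zero Ps(x) are
#' missing; an aggregate Dn of 0 leaves the whole curve undefined.
#'
#' @param mk an `mk_tables` object, or a list with `Dn`, `Ds` scalars and
#'   `Pn_x`, `Ps_x` per-bin count vectors plus `bins`.
#' @return data.table of class `alpha_curve` with `x` (bin midpoint),
#'   `Pn_x`, `Ps_x` and `alpha`; attributes `Dn`, `Ds`.
#' @export
alpha_x <- function(mk) {
  if (inherits(mk, "mk_tables")) {
    Dn <- sum(mk$genes$Dn); Ds <- sum(mk$genes$Ds)
    pnx <- colSums(mk$Pn_x); psx <- colSums(mk$Ps_x)
    mids <- mk$bins$mids
  } else {
    Dn <- mk$Dn; Ds <- mk$Ds; pnx <- mk$Pn_x; psx <- mk$Ps_x
    mids <- mk$bins$mids
  }
  if (Dn == 0) stop("Dn = 0: alpha(x) undefined")
  alpha <- ifelse(psx > 0, 1 - (Ds / Dn) * (pnx / psx), NA_real_)
  out <- data.table::data.table(x = mids, Pn_x = as.numeric(pnx),
                                Ps_x = as.numeric(psx), alpha = alpha)
  data.table::setattr(out, "Dn", Dn)
  data.table::setattr(out, "Ds", Ds)
  data.table::setattr(out, "class", c("alpha_curve", class(out)))
  out
}

#' Pooled (classical) McDonald-Kreitman alpha
#'
#' alpha = 1 - (Ds * Pn) / (Dn * Ps) on aggregate counts.
#' @param Dn,Ds,Pn,Ps aggregate MK counts.
#' @return scalar alpha (NA when undefined).
#' @export
alpha_pooled <- function(Dn, Ds, Pn, Ps) {
  if (Dn == 0 || Ps == 0) return(NA_real_)
  1 - (Ds * Pn) / (Dn * Ps)
}

.fit_alpha_exp <- function(x, alpha) {
  df <- data.frame(x = x, alpha = alpha)
  a0 <- alpha[length(alpha)]
  b0 <- alpha[1] - a0
  if (!is.finite(b0) || b0 == 0) b0 <- -0.1
  fit <- try(minpack.lm::nlsLM(
    alpha ~ a + b * exp(-c * x), data = df,
    start = list(a = a0, b = b0, c = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) return(NULL)
  list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
       alpha_asymptotic = cf[["a"]] + cf[["b"]] * exp(-cf[["c"]]))
}

#' Asymptotic alpha from an alpha(x) curve
#'
#' Fits alpha(x) = a + b exp(-c x) by nonlinear least squares and reports
#' the asymptotic estimate alpha(1) = a + b exp(-c), which removes the
#' downward bias that segregating slightly deleterious variants impose on
#' the pooled estimate. When the exponential fit fails (degenerate or
#' flat curves) the function falls back to a linear extrapolation to
#' x = 1 and flags it.
#'
#' @param curve an [alpha_x()] curve (rows with missing alpha dropped).
#' @param mk optional `mk_tables` object enabling gene bootstrap.
#' @param n_boot bootstrap replicates for the confidence interval
#'   (resampling genes when `mk` is given, otherwise bins); 0 disables.
#' @param conf confidence level (default 0.95).
#' @return list with `a`, `b`, `c` (NA for the linear fallback),
#'   `alpha_asymptotic`, `method` (`"exponential"` or `"linear"`), and
#'   `ci` when bootstrapped.
#' @export
fit_asymptotic_alpha <- function(curve, mk = NULL, n_boot = 0, conf = 0.95) {
  cv <- curve[!is.na(curve$alpha), ]
  if (nrow(cv) < 4) stop("need at least 4 non-missing alpha bins")
  point <- .fit_alpha_exp(cv$x, cv$alpha)
  if (is.null(point)) {
    lf <- stats::lm(alpha ~ x, data = cv)
    point <- list(a = NA_real_, b = NA_real_, c = NA_real_,
                  alpha_asymptotic =
                    unname(stats::predict(lf, data.frame(x = 1))))
    method <- "linear"
  } else method <- "exponential"

  ci <- NULL
  if (n_boot > 0) {
    boots <- numeric(0)
    for (r in seq_len(n_boot)) {
      if (!is.null(mk)) {
        idx <- sample.int(nrow(mk$genes), replace = TRUE)
        agg <- list(Dn = sum(mk$genes$Dn[idx]), Ds = sum(mk$genes$Ds[idx]),
                    Pn_x = colSums(mk$Pn_x[idx, , drop = FALSE]),
                    Ps_x = colSums(mk$Ps_x[idx, , drop = FALSE]),
                    bins = mk$bins)
        if (agg$Dn == 0) next
        bc <- alpha_x(agg)
        bc <- bc[!is.na(bc$alpha), ]
      } else {
        bc <- cv[sample.int(nrow(cv), replace = TRUE), ]
      }
      if (nrow(bc) < 4) next
      bf <- .fit_alpha_exp(bc$x, bc$alpha)
      if (!is.null(bf) && is.finite(bf$alpha_asymptotic))
        boots <- c(boots, bf$alpha_asymptotic)
    }
    if (length(boots) >= 10)
      ci <- unname(stats::quantile(boots, c((1 - conf) / 2, (1 + conf) / 2)))
  }
  c(point, list(method = method, ci = ci))
}

#' Direction of selection (DoS) per gene
#'
#' DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps); positive under adaptive evolution,
#' negative when slightly deleterious variants segregate. Genes without
#' at least one substituted and one polymorphic site are undefined (`NA`).
#'
#' @param tab per-gene MK table (`mk_tables$genes` or any data.frame with
#'   `Dn`, `Ds`, `Pn`, `Ps` columns).
#' @return numeric vector of DoS values.
#' @export
dos <- function(tab) {
  D <- tab$Dn + tab$Ds
  P <- tab$Pn + tab$Ps
  ifelse(D > 0 & P > 0, tab$Dn / D - tab$Pn / P, NA_real_)
}

#' Percentile gene sets of the DoS distribution
#'
#' @param dos_values per-gene DoS (NAs ignored).
#' @param gene_ids matching gene identifiers.
#' @param lower_q,upper_q tail percentiles (defaults 0.025 and 0.975).
#' @return list with `lower`/`upper` gene id vectors, `median`, and the
#'   percentile `thresholds`. With fewer than 40 informative genes a
#'   warning is issued and the tails are empty.
#' @export
dos_gene_sets <- function(dos_values, gene_ids, lower_q = 0.025,
                          upper_q = 0.975) {
  ok <- !is.na(dos_values)
  dv <- dos_values[ok]
  ids <- gene_ids[ok]
  med <- stats::median(dv)
  if (length(dv) < 40) {
    warning("fewer than 40 genes with defined DoS; tails not reported")
    return(list(lower = character(0), upper = character(0), median = med,
                thresholds = c(NA_real_, NA_real_)))
  }
  thr <- stats::quantile(dv, c(lower_q, upper_q), type = 7, names = FALSE)
  list(lower = ids[dv < thr[1]], upper = ids[dv > thr[2]],
       median = med, thresholds = thr)
}
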