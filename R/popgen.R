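## Windowed nucleotide diversity and Weir-Cockerham Fst.
##
## Both statistics follow the sliding-window protocol of common VCF
## tooling: windows are 1-based inclusive, anchored at position 1 and
## advanced by the step size; windowed Fst is the ratio-of-sums of the
## Weir & Cockerham (1984) variance components a (among populations),
## b (among individuals within populations) and c (within individuals).

#' Per-site nucleotide diversity
#'
#' With \eqn{n} non-missing alleles and \eqn{j} alternate alleles,
#' \deqn{\pi = 2 j (n - j) / (n (n - 1)),} the unbiased expected
#' heterozygosity of the site. Sites with fewer than 2 alleles are
#' skipped (\code{NA}).
#'
#' @param genotypes integer vector of diploid dosages (0/1/2/NA) for one
#'   site, or a sites-by-samples matrix.
#' @return numeric per-site diversity (vector for a matrix input).
#' @examples
#' sitePi(c(0L, 1L, 1L, 2L))
#' @export
sitePi <- function(genotypes) {
    if (is.matrix(genotypes))
        return(apply(genotypes, 1L, sitePi))
    n <- 2L * sum(!is.na(genotypes))
    if (n < 2L) return(NA_real_)
    j <- sum(genotypes, na.rm = TRUE)
    2 * j * (n - j) / (n * (n - 1))
}

# shared window layout: starts anchored at 1, advancing by step, covering
# the scaffold span
.windows <- function(span, window, step) {
    starts <- seq.int(1L, max(1L, span), by = step)
    starts <- starts[starts <= span]
    data.frame(start = starts, end = starts + window - 1L)
}

# per-window sums of sorted per-site values via cumulative sums:
# O(sites + windows) instead of windows x sites
.window_sums <- function(pos, val, w) {
    cum <- c(0, cumsum(val))
    lo <- findInterval(w$start - 1L, pos)
    hi <- findInterval(w$end, pos)
    list(sum = cum[hi + 1L] - cum[lo + 1L], n = hi - lo)
}

#' Sliding-window nucleotide diversity
#'
#' Window diversity is the sum of per-site \eqn{\pi} over contained
#' sites divided by the window size in bp (not the site count), so
#' invariant monomorphic sequence dilutes the estimate exactly as it
#' should. Windows within the covered scaffold span with no variants
#' report 0.
#'
#' @param x a \linkS4class{VariantTable}.
#' @param window window size in bp.
#' @param step step size in bp.
#' @param scaffold_lengths optional named vector bounding the covered
#'   span per scaffold; defaults to the last variant position.
#' @return data.frame of scaffold, start, end, n_sites, pi.
#' @export
windowedPi <- function(x, window = 10000L, step = 1000L,
                       scaffold_lengths = NULL) {
    s <- variantSites(x)
    pis <- sitePi(genotypeMatrix(x))
    out <- lapply(unique(as.character(s$scaffold)), function(sc) {
        sel <- as.character(s$scaffold) == sc
        pos <- s$pos[sel]; pv <- pis[sel]
        span <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
            scaffold_lengths[[sc]] else max(pos)
        keep <- !is.na(pv)
        w <- .windows(span, window, step)
        ws <- .window_sums(pos[keep], pv[keep], w)
        w$n_sites <- ws$n
        w$pi <- ws$sum / window
        cbind(scaffold = sc, w)
    })
    do.call(rbind, out)
}

#' Per-site Weir-Cockerham variance components
#'
#' Direct implementation of the 1984 variance decomposition for
#' biallelic sites with observed heterozygosity, unequal sample sizes
#' and \eqn{r} populations. Only populations with at least
#' \code{min_genotypes} non-missing diploid genotypes enter a site; a
#' site with fewer than 2 such populations is uninformative
#' (\code{NA} components).
#'
#' @param x a \linkS4class{VariantTable}.
#' @param min_genotypes minimal non-missing genotypes per population.
#' @return data.frame of scaffold, pos, a, b, c and per-site theta
#'   \eqn{a / (a + b + c)}.
#' @export
wcComponents <- function(x, min_genotypes = 2L) {
    g <- genotypeMatrix(x)
    pops <- samplePopulations(x)[colnames(g)]
    s <- variantSites(x)
    pop_ids <- unique(pops)
    comp <- t(vapply(seq_len(nrow(g)), function(i) {
        gi <- g[i, ]
        n_i <- p_i <- h_i <- numeric()
        for (pp in pop_ids) {
            gp <- gi[pops == pp]
            gp <- gp[!is.na(gp)]
            if (length(gp) < min_genotypes) next
            n_i <- c(n_i, length(gp))
            p_i <- c(p_i, sum(gp) / (2 * length(gp)))
            h_i <- c(h_i, mean(gp == 1L))
        }
        r <- length(n_i)
        if (r < 2L) return(c(NA_real_, NA_real_, NA_real_))
        nbar <- mean(n_i)
        nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
        pbar <- sum(n_i * p_i) / (r * nbar)
        s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(n_i * h_i) / (r * nbar)
        a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
        b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        c(a, b, cc)
    }, numeric(3)))
    data.frame(scaffold = as.character(s$scaffold), pos = s$pos,
               a = comp[, 1L], b = comp[, 2L], c = comp[, 3L],
               theta = comp[, 1L] / (comp[, 1L] + comp[, 2L] + comp[, 3L]))
}

#' Sliding-window Weir-Cockerham Fst
#'
#' Windowed \eqn{\theta} is the ratio-of-sums
#' \eqn{\sum a / \sum (a + b + c)} over informative sites in the window
#' (the behaviour of the windowed Fst mode in standard VCF tooling); a
#' mean-of-per-site-ratios variant is available as a switch. Negative
#' estimates are reported as computed. The genome-wide means of both
#' summaries are returned alongside the windows.
#'
#' @param x a \linkS4class{VariantTable} with >= 2 populations.
#' @param window window size in bp.
#' @param step step size in bp.
#' @param ratio_of_sums use ratio-of-sums (default) or mean of per-site
#'   ratios.
#' @param scaffold_lengths optional named covered-span bounds.
#' @return list with \code{windows} (scaffold, start, end, n_sites,
#'   theta), \code{components} (per-site a, b, c), \code{mean_theta}
#'   (ratio-of-sums over all informative sites) and
#'   \code{mean_site_theta} (mean of per-site ratios).
#' @export
wcFst <- function(x, window = 10000L, step = 1000L, ratio_of_sums = TRUE,
                  scaffold_lengths = NULL) {
    if (length(unique(samplePopulations(x))) < 2L)
        stop("Fst needs at least 2 populations")
    comp <- wcComponents(x)
    out <- lapply(unique(comp$scaffold), function(sc) {
        cs <- comp[comp$scaffold == sc & !is.na(comp$a), , drop = FALSE]
        span <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
            scaffold_lengths[[sc]] else max(comp$pos[comp$scaffold == sc])
        w <- .windows(span, window, step)
        wa <- .window_sums(cs$pos, cs$a, w)
        wabc <- .window_sums(cs$pos, cs$a + cs$b + cs$c, w)
        ct <- cs[is.finite(cs$theta), , drop = FALSE]  # drop 0/0 sites
        wt <- .window_sums(ct$pos, ct$theta, w)
        w$n_sites <- wa$n
        w$theta <- if (ratio_of_sums) wa$sum / wabc$sum
                   else wt$sum / wt$n
        w$theta[w$n_sites == 0L] <- NA_real_
        cbind(scaffold = sc, w)
    })
    ok <- !is.na(comp$a)
    list(windows = do.call(rbind, out), components = comp,
         mean_theta = sum(comp$a[ok]) /
             sum(comp$a[ok] + comp$b[ok] + comp$c[ok]),
         mean_site_theta = mean(comp$theta[ok], na.rm = TRUE))
}
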