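#' Sliding-window GC profile of a sequence
#'
#' GC fraction in windows of \code{window} bp advanced by \code{step}
#' bp, with each window reported at its centre position normalised by
#' the total sequence length. The default 5-bp window with 1-bp step
#' resolves the stem/loop alternation of tRNA genes.
#'
#' @param seq DNA string, at least \code{window} long.
#' @param window,step Window size and step in bp.
#' @param source Label carried on the profile (gene id or aggregate
#'   label).
#' @return Data.frame of class \code{gc_profile} with columns
#'   \code{position} (normalised window centre in [0, 1]) and \code{gc}.
#' @export
gc_profile <- function(seq, window = 5L, step = 1L, source = NA_character_) {
  seq <- toupper(seq)
  .check_alphabet(seq, "ACGTN")
  L <- nchar(seq)
  if (L < window)
    stop("sequence shorter than window", call. = FALSE)
  is_gc <- strsplit(seq, "", fixed = TRUE)[[1]] %in% c("G", "C")
  cs <- c(0, cumsum(is_gc))
  starts <- seq.int(1L, L - window + 1L, by = step)
  gc <- (cs[starts + window] - cs[starts]) / window
  out <- data.frame(position = (starts + (window - 1) / 2) / L, gc = gc)
  structure(out, class = c("gc_profile", "data.frame"),
            window = window, step = step, source = source)
}

#' GC profiles for every gene in a table
#'
#' @param genes Gene record data.frame.
#' @param window,step See \code{\link{gc_profile}}.
#' @param spliced Profile the mature (intron-spliced) sequence instead
#'   of the full genomic sequence.
#' @param include_und Keep Und/NNN records.
#' @return List of \code{gc_profile} objects named by gene id.
#' @export
gene_gc_profiles <- function(genes, window = 5L, step = 1L,
                             spliced = FALSE, include_und = FALSE) {
  genes <- filter_high_confidence(genes, include_und)
  seqs <- if (spliced) splice_introns(genes) else
    stats::setNames(genes$genomic_seq, genes$gene_id)
  lapply(stats::setNames(nm = names(seqs)), function(id)
    gc_profile(seqs[[id]], window, step, source = id))
}

# tricube-weighted local linear regression evaluated at xout; span is
# the fraction of points entering each local fit
.tricube_local_linear <- function(x, y, xout, span = 0.75) {
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) return(mean(y[d == 0]))
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[use] - x0), y[use], w[use])
    unname(fit$coefficients[1L])
  }, numeric(1))
}

#' Aggregate GC profiles across genes
#'
#' Pools per-gene profiles, bins them by normalised position into
#' \code{n_bins} equal-width bins, averages within bins, and smooths
#' the bin means with a tricube-weighted local linear regression (an
#' explicitly pinned loess-type smoother). A pointwise ~95% band
#' (+/- 1.96 SE) is derived from the within-bin variance.
#'
#' @param profiles List of \code{\link{gc_profile}} objects (or a single
#'   one).
#' @param n_bins Number of position bins over [0, 1].
#' @param span Fraction of bins entering each local fit.
#' @return Data.frame of class \code{gc_profile} with columns
#'   \code{position} (bin centres), \code{gc} (bin mean), \code{fit}
#'   (smoothed), \code{se}, \code{lower}, \code{upper}, \code{n}.
#' @export
aggregate_gc <- function(profiles, n_bins = 100L, span = 0.75) {
  if (inherits(profiles, "gc_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to aggregate",
                                   call. = FALSE)
  pos <- unlist(lapply(profiles, `[[`, "position"), use.names = FALSE)
  gc <- unlist(lapply(profiles, `[[`, "gc"), use.names = FALSE)
  bin <- pmin(pmax(ceiling(pos * n_bins), 1L), n_bins)
  keep <- sort(unique(bin))
  mu <- tapply(gc, bin, mean)
  v <- tapply(gc, bin, function(z)
    if (length(z) > 1L) stats::var(z) else 0)
  nb <- tapply(gc, bin, length)
  centre <- (keep - 0.5) / n_bins
  se <- sqrt(unname(v) / unname(nb))
  fit <- .tricube_local_linear(centre, unname(mu), centre, span)
  out <- data.frame(position = centre, gc = unname(mu), fit = fit,
                    se = se, lower = fit - 1.96 * se,
                    upper = fit + 1.96 * se, n = unname(nb))
  structure(out, class = c("gc_profile", "data.frame"),
            window = attr(profiles[[1]], "window"),
            step = attr(profiles[[1]], "step"), source = "aggregate",
            span = span, n_bins = n_bins)
}

#' Species-by-anticodon abundance matrix
#'
#' Gene counts by (species, anticodon) over the full 64-anticodon
#' space. Initiator Met genes are merged into the CAT column in the
#' canonical 64-column view and additionally reported under their own
#' \code{iMet_CAT} column in a supplementary 65-column view. The absent
#' set is the columns of the 64-column view whose total is zero.
#'
#' @param genes Gene record data.frame.
#' @param include_und Keep Und/NNN records (dropped by default and never
#'   counted in the 64-anticodon space).
#' @return List of class \code{abundance_matrix}: \code{matrix} (64
#'   columns), \code{matrix65}, \code{species_totals},
#'   \code{anticodon_totals}, \code{absent}, \code{present}.
#' @export
abundance_matrix <- function(genes, include_und = FALSE) {
  genes <- filter_high_confidence(genes, include_und)
  genes <- genes[genes$anticodon %in% ANTICODONS, , drop = FALSE]
  sp <- factor(genes$species)
  ac <- factor(genes$anticodon, levels = ANTICODONS)
  m64 <- as.matrix(table(sp, ac))
  imet <- genes$isotype == "iMet"
  ac65 <- as.character(genes$anticodon)
  ac65[imet] <- "iMet_CAT"
  m65 <- as.matrix(table(sp, factor(ac65,
                                    levels = c(ANTICODONS, "iMet_CAT"))))
  tot_ac <- colSums(m64)
  structure(list(matrix = m64, matrix65 = m65,
                 species_totals = rowSums(m64),
                 anticodon_totals = tot_ac,
                 absent = names(tot_ac)[tot_ac == 0],
                 present = names(tot_ac)[tot_ac > 0]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$matrix), "species x 64 anticodons;",
      length(x$present), "present,", length(x$absent), "absent\n")
  invisible(x)
}

#' Intron statistics per species and globally
#'
#' The I/T ratio is the percentage of intron-containing tRNA genes among
#' all tRNA genes of a species. The global histogram is over individual
#' intron lengths; the mode is the smallest length achieving the maximum
#' frequency.
#'
#' @param genes Gene record data.frame.
#' @param include_und Keep Und/NNN records.
#' @return List of class \code{intron_stats}: \code{per_species}
#'   (data.frame species, n_genes, n_intron_genes, it_ratio in percent;
#'   NA for species with zero genes), \code{lengths}, \code{histogram},
#'   \code{mean_length}, \code{mode_length}, \code{per_isotype}.
#' @export
intron_stats <- function(genes, include_und = FALSE) {
  genes <- filter_high_confidence(genes, include_und)
  ni <- n_introns(genes)
  has <- ni > 0L
  per_sp <- do.call(rbind, lapply(split(has, genes$species), function(h)
    data.frame(n_genes = length(h), n_intron_genes = sum(h),
               it_ratio = if (length(h)) 100 * sum(h) / length(h)
                          else NA_real_)))
  per_sp <- data.frame(species = rownames(per_sp), per_sp,
                       row.names = NULL, stringsAsFactors = FALSE)
  ilen <- unlist(lapply(genes$introns[has], function(sp)
    sp$end - sp$start + 1L), use.names = FALSE)
  if (is.null(ilen)) ilen <- integer(0)
  hist <- table(ilen)
  mode_len <- if (length(hist))
    min(as.integer(names(hist)[hist == max(hist)])) else NA_integer_
  iso <- table(factor(genes$isotype[has]))
  per_iso <- data.frame(isotype = names(iso),
                        n_intron_genes = as.integer(iso),
                        fraction = if (sum(iso) > 0)
                          as.numeric(iso) / sum(iso) else numeric(0),
                        stringsAsFactors = FALSE)
  structure(list(per_species = per_sp, lengths = ilen, histogram = hist,
                 mean_length = if (length(ilen)) mean(ilen) else NA_real_,
                 mode_length = mode_len, per_isotype = per_iso),
            class = "intron_stats")
}

#' @export
print.intron_stats <- function(x, ...) {
  cat("intron_stats:", length(x$lengths), "introns; mode",
      x$mode_length, "bp; mean", round(x$mean_length, 2), "bp\n")
  print(x$per_species)
  invisible(x)
}

#' Correlation between per-species gene counts and genome size
#'
#' Pearson correlation with a two-sided p-value from the t distribution
#' on n - 2 degrees of freedom, plus the ordinary least-squares
#' regression of counts on genome size.
#'
#' @param counts Named numeric vector of per-species tRNA gene counts.
#' @param sizes Named numeric vector of genome sizes (bp); matched to
#'   \code{counts} by name when both are named.
#' @return List of class \code{correlation_result}: \code{r},
#'   \code{p_value}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}. All NA (with a message in \code{note}) when either
#'   variable has zero variance.
#' @export
genome_size_correlation <- function(counts, sizes) {
  if (!is.null(names(counts)) && !is.null(names(sizes)))
    sizes <- sizes[names(counts)]
  n <- length(counts)
  if (n < 3L || n != length(sizes))
    stop("need matched vectors with n >= 3", call. = FALSE)
  if (stats::sd(counts) == 0 || stats::sd(sizes) == 0)
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n = n,
                          note = "zero variance"),
                     class = "correlation_result"))
  ct <- stats::cor.test(sizes, counts, method = "pearson",
                        alternative = "two.sided")
  fit <- stats::lm(counts ~ sizes)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared, n = n,
                 note = NA_character_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$r)) cat("correlation undefined:", x$note, "\n")
  else cat(sprintf("r = %.3f (p = %.3g), R^2 = %.3f, n = %d\n",
                   x$r, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Gene-length distribution
#'
#' Integer histogram of genomic gene lengths (end - start + 1,
#' introns included) with all tied modes reported; tRNA gene-length
#' distributions are typically bimodal.
#'
#' @param genes Gene record data.frame.
#' @param include_und Keep Und/NNN records.
#' @return List of class \code{length_distribution}: \code{histogram},
#'   \code{min}, \code{max}, \code{modes} (all lengths achieving the
#'   maximum frequency, ascending).
#' @export
length_distribution <- function(genes, include_und = FALSE) {
  genes <- filter_high_confidence(genes, include_und)
  len <- genes$end - genes$start + 1L
  hist <- table(len)
  modes <- if (length(hist))
    sort(as.integer(names(hist)[hist == max(hist)])) else integer(0)
  structure(list(histogram = hist,
                 min = if (length(len)) min(len) else NA_integer_,
                 max = if (length(len)) max(len) else NA_integer_,
                 modes = modes),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat("gene lengths:", x$min, "-", x$max, "bp; mode(s)",
      paste(x$modes, collapse = ", "), "bp\n")
  invisible(x)
}
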