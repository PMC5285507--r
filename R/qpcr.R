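## qPCR enrichment math: delta-delta-Ct relative abundance (knockdown vs
## control, normalised to a reference amplicon), percent-of-input
## enrichment for RNA immunoprecipitation, and replicate pulldown ratios.

#' Read a Ct table from TSV
#'
#' Expected columns: `sample`, `amplicon`, `ct` (cycles) and optionally
#' `replicate`. Ct values must be positive.
#'
#' @param path tab-separated Ct table.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  req <- c("sample", "amplicon", "ct")
  missing <- setdiff(req, names(ct))
  if (length(missing)) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) stop("Ct values must be positive")
  if (is.null(ct$replicate)) ct$replicate <- 1L
  ct
}

## mean Ct across technical replicates for one (sample, amplicon);
## errors identify the missing pair
mean_ct <- function(ct, sample, amplicon) {
  x <- ct$ct[ct$sample == sample & ct$amplicon == amplicon]
  if (length(x) == 0L) {
    stop(sprintf("no Ct for amplicon '%s' in sample '%s'", amplicon, sample))
  }
  mean(x)
}

#' Relative abundance by the delta-delta-Ct method
#'
#' Fold change of a target amplicon in a treated sample relative to a
#' control sample, normalised to a reference amplicon (18S rRNA by
#' default):
#' `fold = E^-[(Ct_target,t - Ct_ref,t) - (Ct_target,c - Ct_ref,c)]`
#' with amplification efficiency `E` (2 assumes perfect doubling).
#' Technical-replicate Cts are averaged before the differences; setting
#' `per_replicate = TRUE` instead pairs replicates by index, computes a
#' fold change per replicate, and reports their mean and SD. Fold > 1
#' means accumulation in the treated sample.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param treated,control sample names.
#' @param target character vector of target amplicons.
#' @param reference reference amplicon name.
#' @param efficiency amplification efficiency per cycle.
#' @param per_replicate compute per-replicate fold changes (see above).
#' @return data.frame with one row per target: `target`, `ddct`, `fold`
#'   (and `fold_sd` when `per_replicate`).
#' @export
ddct_relative_abundance <- function(ct, treated, control, target,
                                    reference = "18S", efficiency = 2,
                                    per_replicate = FALSE) {
  ct <- validate_ct_table(ct)
  if (efficiency <= 1) stop("efficiency must exceed 1")
  rows <- lapply(target, function(tg) {
    if (!per_replicate) {
      ddct <- (mean_ct(ct, treated, tg) - mean_ct(ct, treated, reference)) -
        (mean_ct(ct, control, tg) - mean_ct(ct, control, reference))
      data.frame(target = tg, ddct = ddct, fold = efficiency^(-ddct))
    } else {
      one <- function(sample, amplicon) {
        x <- ct[ct$sample == sample & ct$amplicon == amplicon, , drop = FALSE]
        if (nrow(x) == 0L) {
          stop(sprintf("no Ct for amplicon '%s' in sample '%s'",
                       amplicon, sample))
        }
        stats::setNames(x$ct, x$replicate)
      }
      tt <- one(treated, tg); tr <- one(treated, reference)
      ctg <- one(control, tg); cr <- one(control, reference)
      reps <- Reduce(intersect, list(names(tt), names(tr), names(ctg),
                                     names(cr)))
      if (!length(reps)) stop("no complete replicate across the four series")
      f <- efficiency^(-((tt[reps] - tr[reps]) - (ctg[reps] - cr[reps])))
      data.frame(target = tg, ddct = mean(-log(f, efficiency)),
                 fold = mean(f),
                 fold_sd = if (length(f) > 1) stats::sd(f) else NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent-of-input enrichment for RIP-qPCR
#'
#' Enrichment of a target in an immunoprecipitated (IP) sample relative to
#' an input sample reverse-transcribed from a fraction of the lysate:
#' `%input = 100 * E^[(Ct_input - log_E(1/input_fraction)) - Ct_ip]`.
#' The log term adjusts the input Ct to what the whole lysate would have
#' given. Replicate Cts are averaged first. The quantity is invariant
#' under adding a constant to both Cts of a target (shift invariance).
#'
#' @param ct Ct table.
#' @param ip,input sample names of the IP and the diluted input.
#' @param target character vector of target amplicons.
#' @param input_fraction fraction of lysate used for the input, in (0, 1].
#' @param efficiency amplification efficiency per cycle.
#' @return data.frame with `target`, `ct_ip`, `ct_input_adjusted`,
#'   `percent_input`.
#' @export
percent_input_enrichment <- function(ct, ip, input, target,
                                     input_fraction = 0.1, efficiency = 2) {
  ct <- validate_ct_table(ct)
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must be in (0, 1]")
  }
  if (efficiency <= 1) stop("efficiency must exceed 1")
  adj <- log(1 / input_fraction, base = efficiency)
  rows <- lapply(target, function(tg) {
    ct_ip <- mean_ct(ct, ip, tg)
    ct_in <- mean_ct(ct, input, tg) - adj
    data.frame(target = tg, ct_ip = ct_ip, ct_input_adjusted = ct_in,
               percent_input = 100 * efficiency^(ct_in - ct_ip))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of paired pulldown signals with replicate spread
#'
#' Per-replicate ratio of two aligned signal series (e.g. pulldown
#' efficiency in knockdown versus control cells, or signal relative to a
#' BSA control), reported as mean and standard deviation over replicates.
#'
#' @param signal_a,signal_b numeric vectors of paired replicate signals;
#'   `signal_b` must be strictly positive.
#' @return list of class `pulldown_ratio` with `ratios`, `mean`, `sd`
#'   (NA for a single replicate), `n`.
#' @export
pulldown_ratio <- function(signal_a, signal_b) {
  if (length(signal_a) != length(signal_b)) {
    stop("replicate series must be aligned (equal length)")
  }
  if (any(!is.finite(signal_b)) || any(signal_b <= 0)) {
    stop("denominator signals must be strictly positive")
  }
  r <- signal_a / signal_b
  structure(list(ratios = r, mean = mean(r),
                 sd = if (length(r) > 1) stats::sd(r) else NA_real_,
                 n = length(r)),
            class = "pulldown_ratio")
}

#' @export
print.pulldown_ratio <- function(x, ...) {
  cat(sprintf("pulldown ratio: mean %.4f, SD %s (n = %d)\n", x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd), x$n))
  invisible(x)
}
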