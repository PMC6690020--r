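#' Partition repeats by CpG-island content
#'
#' @param repeats Repeat table ([read_rmsk()]).
#' @param cgis CpG-island intervals.
#' @return List with elements `with_cgi` and `without_cgi`; an element
#'   is in `with_cgi` iff it overlaps any CGI by >= 1 bp. The two parts
#'   partition the input.
#' @export
split_by_cgi <- function(repeats, cgis) {
  if (!nrow(repeats))
    return(list(with_cgi = repeats, without_cgi = repeats))
  hit <- rep(FALSE, nrow(repeats))
  if (nrow(cgis)) {
    ov <- GenomicRanges::findOverlaps(.gr(repeats), .gr(cgis),
                                      ignore.strand = TRUE)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  list(with_cgi = repeats[hit, , drop = FALSE],
       without_cgi = repeats[!hit, , drop = FALSE])
}

#' Per-element methylation summary
#'
#' Summarizes the methylation level of the (depth-filtered) sites
#' contained in each repeat element. Elements without any covered site
#' get `NA`.
#'
#' @param repeats Repeat table.
#' @param sites Site table (CpG context recommended).
#' @param stat `"mean"` or `"median"`.
#' @return The repeat table with added columns `n_sites` and `beta`.
#' @export
element_methylation <- function(repeats, sites, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  out <- repeats
  out$n_sites <- 0L
  out$beta <- NA_real_
  if (!nrow(repeats) || !nrow(sites)) return(out)
  beta <- methyl_beta(sites)
  ov <- GenomicRanges::findOverlaps(.gr_sites(sites), .gr(repeats),
                                    ignore.strand = TRUE)
  if (!length(ov)) return(out)
  sh <- S4Vectors::subjectHits(ov); qh <- S4Vectors::queryHits(ov)
  n <- table(sh)
  out$n_sites[as.integer(names(n))] <- as.integer(n)
  val <- tapply(beta[qh], sh, f, na.rm = TRUE)
  out$beta[as.integer(names(val))] <- val
  out
}

# signed offset of each site from the element 5' end, in element orientation
.element_offsets <- function(repeats, sites, flank_bp) {
  ext <- data.frame(chrom = repeats$chrom,
                    start = pmax(repeats$start - flank_bp, 0L),
                    end = repeats$end + flank_bp, strand = ".")
  ov <- GenomicRanges::findOverlaps(.gr_sites(sites), .gr(ext),
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  pos <- sites$pos[qh]
  s <- repeats$start[sh]; e <- repeats$end[sh]
  minus <- repeats$strand[sh] == "-"
  t <- ifelse(minus, (e - 1L) - pos, pos - s)
  list(site = qh, element = sh, offset = t, len = e - s)
}

#' Scaled metaprofile of methylation across repeat elements
#'
#' Element bodies are rescaled to `body_bins` bins (a site at offset `o`
#' in an element of length `L` maps to bin `floor(body_bins * o / L)`),
#' flanks of fixed width `flank_bp` are split into `flank_bins` bins,
#' and minus-strand elements are flipped so profiles are in element
#' orientation. Per bin, the mean methylation level over all sites of
#' all elements is reported, together with a LOESS-smoothed series
#' (degree-1 local fits, tricube weights, the given span). Bins without
#' sites are reported with `NA`, never zero.
#'
#' @param repeats Repeat table (typically one class or subtype).
#' @param sites Depth-filtered site table (CpG context recommended).
#' @param body_bins Number of scaled body bins (default 100).
#' @param flank_bp Flank width in bp (default 100).
#' @param flank_bins Number of bins per flank (default 20).
#' @param loess_span LOESS span (default 0.3).
#' @param min_length Elements shorter than this are discarded
#'   (default `body_bins`, so each body bin can hold a site).
#' @return `data.frame` with `bin_kind` (`up`/`body`/`down`),
#'   `bin_index`, `n_sites`, `mean_beta`, `loess_beta`; attribute
#'   `"n_elements"` gives the number of contributing elements.
#' @export
metaprofile <- function(repeats, sites, body_bins = 100, flank_bp = 100,
                        flank_bins = 20, loess_span = 0.3,
                        min_length = body_bins) {
  rep_use <- repeats[(repeats$end - repeats$start) >= min_length, ,
                     drop = FALSE]
  grid <- data.frame(
    bin_kind = rep(c("up", "body", "down"),
                   c(flank_bins, body_bins, flank_bins)),
    bin_index = c(seq_len(flank_bins), seq_len(body_bins),
                  seq_len(flank_bins)),
    stringsAsFactors = FALSE)
  grid$n_sites <- 0L
  grid$mean_beta <- NA_real_
  grid$loess_beta <- NA_real_
  attr(grid, "n_elements") <- nrow(rep_use)
  if (!nrow(rep_use)) {
    warning("metaprofile: no elements after length filtering")
    return(grid)
  }
  off <- .element_offsets(rep_use, sites, flank_bp)
  if (!length(off$site)) return(grid)
  beta <- methyl_beta(sites)[off$site]
  t <- off$offset; L <- off$len
  kind <- ifelse(t < 0, "up", ifelse(t < L, "body", "down"))
  bw <- flank_bp / flank_bins
  idx <- integer(length(t))
  idx[kind == "up"] <- pmin(floor((t[kind == "up"] + flank_bp) / bw),
                            flank_bins - 1) + 1L
  idx[kind == "body"] <- pmin(floor(body_bins * t[kind == "body"] /
                                      L[kind == "body"]),
                              body_bins - 1) + 1L
  idx[kind == "down"] <- pmin(floor((t[kind == "down"] - L[kind == "down"]) /
                                      bw),
                              flank_bins - 1) + 1L
  key <- paste(kind, idx)
  gkey <- paste(grid$bin_kind, grid$bin_index)
  n <- table(key)
  grid$n_sites[match(names(n), gkey)] <- as.integer(n)
  mb <- tapply(beta, key, mean, na.rm = TRUE)
  grid$mean_beta[match(names(mb), gkey)] <- mb
  # smooth in plot order: up | body | down
  x <- seq_len(nrow(grid))
  def <- !is.na(grid$mean_beta)
  if (sum(def) >= 4) {
    fit <- loess(grid$mean_beta[def] ~ x[def], span = loess_span, degree = 1)
    grid$loess_beta[def] <- predict(fit, x[def])
  } else {
    grid$loess_beta <- grid$mean_beta
  }
  grid
}

#' Inner vs. outer-flank methylation statistics of a repeat class
#'
#' The inner pool is every (depth-filtered) site inside the given
#' elements; the outer pool is every site within `flank_bp` outside
#' either element boundary, excluding sites that fall inside any element
#' of `exclude` (by default the given elements themselves; pass the full
#' repeat annotation to also exclude flank sites inside neighbouring
#' repeats of other classes). Pools aggregate sites, not per-element
#' means.
#'
#' @param repeats Repeat table (typically one class).
#' @param sites Depth-filtered site table.
#' @param flank_bp Flank width (default 100).
#' @param exclude Repeat table whose elements mask the outer pool
#'   (default `repeats`).
#' @return One-row `data.frame`: `n_inner`, `inner_mean`, `inner_sd`,
#'   `n_outer`, `outer_mean`, `outer_sd`, `difference`
#'   (`outer_mean - inner_mean`), `flank_bp`. Means are `NA` when a pool
#'   is empty.
#' @export
inner_outer_stats <- function(repeats, sites, flank_bp = 100,
                              exclude = repeats) {
  beta <- methyl_beta(sites)
  gs <- .gr_sites(sites)
  inner_hit <- rep(FALSE, nrow(sites))
  outer_hit <- rep(FALSE, nrow(sites))
  if (nrow(repeats)) {
    ov <- GenomicRanges::findOverlaps(gs, .gr(repeats), ignore.strand = TRUE)
    inner_hit[unique(S4Vectors::queryHits(ov))] <- TRUE
    fl <- data.frame(
      chrom = rep(repeats$chrom, 2),
      start = c(pmax(repeats$start - flank_bp, 0L), repeats$end),
      end = c(repeats$start, repeats$end + flank_bp),
      strand = ".")
    fl <- fl[fl$start < fl$end, , drop = FALSE]   # element at chromosome start
    if (nrow(fl)) {
      ovf <- GenomicRanges::findOverlaps(gs, .gr(fl), ignore.strand = TRUE)
      outer_hit[unique(S4Vectors::queryHits(ovf))] <- TRUE
    }
    if (nrow(exclude)) {
      ove <- GenomicRanges::findOverlaps(gs, .gr(exclude),
                                         ignore.strand = TRUE)
      outer_hit[unique(S4Vectors::queryHits(ove))] <- FALSE
    }
  }
  inner <- beta[inner_hit & !is.na(beta)]
  outer <- beta[outer_hit & !is.na(beta)]
  data.frame(n_inner = length(inner),
             inner_mean = if (length(inner)) mean(inner) else NA_real_,
             inner_sd = if (length(inner) > 1) sd(inner) else NA_real_,
             n_outer = length(outer),
             outer_mean = if (length(outer)) mean(outer) else NA_real_,
             outer_sd = if (length(outer) > 1) sd(outer) else NA_real_,
             difference = (if (length(outer)) mean(outer) else NA_real_) -
               (if (length(inner)) mean(inner) else NA_real_),
             flank_bp = flank_bp)
}

#' Per-subtype methylation summary
#'
#' For each repeat subtype (`rep_name`): element count, median element
#' length, median of per-element median methylation, and a
#' classification as `hypo` (median < `hypo_cut`), `hyper`
#' (median >= `hyper_cut`) or `intermediate`.
#'
#' @param repeats Repeat table.
#' @param sites Depth-filtered site table.
#' @param hypo_cut,hyper_cut Classification cutoffs (defaults 0.25 and
#'   0.75, mirroring the methylation-level quartile bins).
#' @return `data.frame` with `rep_name`, `rep_class`, `n`,
#'   `median_length`, `median_beta`, `classification`.
#' @export
subtype_summary <- function(repeats, sites, hypo_cut = 0.25,
                            hyper_cut = 0.75) {
  em <- element_methylation(repeats, sites, stat = "median")
  em$length <- em$end - em$start
  parts <- split(em, em$rep_name)
  out <- do.call(rbind, lapply(parts, function(g) {
    mb <- median(g$beta, na.rm = TRUE)
    data.frame(rep_name = g$rep_name[1], rep_class = g$rep_class[1],
               n = nrow(g), median_length = median(g$length),
               median_beta = mb,
               classification = if (is.na(mb)) NA_character_
                 else if (mb < hypo_cut) "hypo"
                 else if (mb >= hyper_cut) "hyper"
                 else "intermediate",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
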