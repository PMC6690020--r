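#' @import data.table
#' @importFrom stats median quantile sd rbeta rbinom rnbinom rnorm runif
#'   p.adjust dhyper cor pt loess predict setNames aggregate
#' @importFrom utils head tail packageVersion
NULL

# All in-memory intervals use the 0-based half-open convention; conversions
# to/from 1-based formats happen only in readers and writers.

.CONTEXTS   <- c("CpG", "CHG", "CHH")
.STRANDS    <- c("+", "-", ".")
.REP_CLASSES <- c("LINE", "SINE", "LTR", "Simple_repeat", "Low_complexity",
                  "Satellite", "DNA", "Other")

#' Construct a table of genomic intervals
#'
#' Intervals are plain `data.frame`s with columns `chrom`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive) throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end` required.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  strand = rep_len(as.character(strand), length(chrom)),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, where = "intervals") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("%s: invalid interval(s) at row(s) %s (need 0 <= start < end)",
                 where, paste(head(bad, 5), collapse = ", ")))
  }
  if (!all(x$strand %in% .STRANDS)) {
    stop(sprintf("%s: strand must be one of %s", where,
                 paste(.STRANDS, collapse = " ")))
  }
  invisible(x)
}

# internal: data.frame intervals -> GRanges (GRanges is 1-based closed)
.gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x))
      ifelse(x$strand == ".", "*", x$strand) else "*")
}

# internal: methylation sites -> width-1 GRanges at pos (0-based)
.gr_sites <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L))
}

#' Per-site methylation level and depth
#'
#' @param sites A methylation-site table (see [read_cytosine_report()]).
#' @return `site_depth()`: integer read depth `n_meth + n_unmeth`.
#'   `methyl_beta()`: methylation level `n_meth / depth` in `[0, 1]`,
#'   `NA` where depth is zero.
#' @export
site_depth <- function(sites) sites$n_meth + sites$n_unmeth

#' @rdname site_depth
#' @export
methyl_beta <- function(sites) {
  depth <- site_depth(sites)
  ifelse(depth > 0, sites$n_meth / depth, NA_real_)
}

#' Read a Bismark-style cytosine report
#'
#' Parses the 7-column tab-separated cytosine report (chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide). Positions are converted to the package's 0-based
#' convention.
#'
#' @param path Path to the report.
#' @param context Optional context filter: subset of `"CpG"`, `"CHG"`,
#'   `"CHH"`. `NULL` keeps all contexts.
#' @param tolerant If `TRUE`, malformed rows are dropped with a warning
#'   instead of raising an error.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_unmeth`.
#' @export
read_cytosine_report <- function(path, context = NULL, tolerant = FALSE) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)),
                          fill = TRUE)
  if (ncol(dt) < 6)
    stop("cytosine report format error: expected >= 6 tab-separated columns ",
         "(chromosome, position, strand, count-methylated, count-unmethylated, ",
         "context); got ", ncol(dt))
  x <- data.frame(chrom   = as.character(dt[[1]]),
                  pos     = suppressWarnings(as.integer(dt[[2]])) - 1L,
                  strand  = as.character(dt[[3]]),
                  n_meth  = suppressWarnings(as.integer(dt[[4]])),
                  n_unmeth = suppressWarnings(as.integer(dt[[5]])),
                  context = as.character(dt[[6]]),
                  stringsAsFactors = FALSE)
  x$context[x$context %in% c("CG", "CpG")] <- "CpG"
  bad <- which(is.na(x$pos) | is.na(x$n_meth) | is.na(x$n_unmeth) |
               x$n_meth < 0 | x$n_unmeth < 0 | x$pos < 0 |
               !(x$strand %in% c("+", "-")) | !(x$context %in% .CONTEXTS))
  if (length(bad)) {
    msg <- sprintf("cytosine report %s: %d malformed line(s), first at line %d",
                   path, length(bad), bad[1])
    if (tolerant) {
      warning(msg, "; dropped")
      x <- x[-bad, , drop = FALSE]
    } else stop(msg)
  }
  if (!is.null(context)) {
    stopifnot(all(context %in% .CONTEXTS))
    x <- x[x$context %in% context, , drop = FALSE]
  }
  x <- x[, c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")]
  rownames(x) <- NULL
  x
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; emits 1-based positions and a
#' context-consistent placeholder trinucleotide column.
#'
#' @param sites Site table as returned by [read_cytosine_report()].
#' @param path Output path.
#' @export
write_cytosine_report <- function(sites, path) {
  tri <- c(CpG = "CGA", CHG = "CAG", CHH = "CAT")[sites$context]
  dt <- data.table::data.table(sites$chrom, sites$pos + 1L, sites$strand,
                               sites$n_meth, sites$n_unmeth, sites$context,
                               tri)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED is already 0-based half-open; coordinates are kept as-is. The strand
#' is `"."` when absent.
#'
#' @param path Path to the BED file.
#' @return Interval `data.frame` (see [genomic_intervals()]), plus a `name`
#'   column when present in the input.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3)
    stop("BED format error: expected >= 3 columns, got ", ncol(dt))
  x <- data.frame(chrom = as.character(dt[[1]]),
                  start = as.integer(dt[[2]]),
                  end   = as.integer(dt[[3]]),
                  strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
                  stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) x$name <- as.character(dt[[4]])
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(sprintf("BED %s: start >= end at line %d", path, bad[1]))
  validate_intervals(x, where = paste0("BED ", path))
  x
}

#' Write intervals as BED
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  nm <- if ("name" %in% names(x)) x$name else "."
  dt <- data.table::data.table(x$chrom, x$start, x$end, nm, 0L, x$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

.map_rep_class <- function(cls) {
  out <- sub("[?/].*$", "", cls)           # "SINE?" or "SINE/Alu" -> "SINE"
  unknown <- !(out %in% .REP_CLASSES)
  if (any(unknown)) {
    warning(sprintf("%d repeat(s) with class outside the known vocabulary (%s) mapped to Other",
                    sum(unknown),
                    paste(unique(out[unknown]), collapse = ", ")))
    out[unknown] <- "Other"
  }
  out
}

#' Read a repeat annotation table
#'
#' Supports two dialects: `"ucsc_table"` (rmsk table export: tab-separated
#' with columns genoName, genoStart, genoEnd, strand, repName, repClass,
#' repFamily; 0-based half-open) and `"repeatmasker_out"` (whitespace-
#' separated RepeatMasker `.out` with 1-based inclusive begin/end). Both are
#' normalized to 0-based half-open coordinates, and repeat classes are
#' mapped to the closed vocabulary `LINE, SINE, LTR, Simple_repeat,
#' Low_complexity, Satellite, DNA, Other` (suffixes such as `"?"` or a
#' `"/family"` part are stripped; anything else maps to `Other` with a
#' warning).
#'
#' @param path Path to the annotation.
#' @param dialect `"ucsc_table"` or `"repeatmasker_out"`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class`, `rep_family`.
#' @export
read_rmsk <- function(path, dialect = c("ucsc_table", "repeatmasker_out")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown rmsk dialect: ",
                                               dialect[1]))
  if (dialect == "ucsc_table") {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    need <- c("genoName", "genoStart", "genoEnd", "strand",
              "repName", "repClass", "repFamily")
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stop("rmsk table missing column(s): ", paste(miss, collapse = ", "))
    x <- data.frame(chrom = as.character(dt$genoName),
                    start = as.integer(dt$genoStart),
                    end   = as.integer(dt$genoEnd),
                    strand = ifelse(dt$strand %in% c("+", "-"),
                                    as.character(dt$strand), "."),
                    rep_name = as.character(dt$repName),
                    rep_class = as.character(dt$repClass),
                    rep_family = as.character(dt$repFamily),
                    stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!grepl("^\\s*($|SW|score)", ln)]   # header lines of .out
    if (!length(ln)) {
      x <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), rep_name = character(),
                      rep_class = character(), rep_family = character(),
                      stringsAsFactors = FALSE)
      return(x)
    }
    f <- strsplit(trimws(ln), "\\s+")
    get <- function(i) vapply(f, `[`, "", i)
    cls <- get(11)
    fam <- ifelse(grepl("/", cls), sub("^[^/]*/", "", cls), "")
    x <- data.frame(chrom = get(5),
                    start = as.integer(get(6)) - 1L,   # 1-based incl -> 0-based
                    end   = as.integer(get(7)),
                    strand = ifelse(get(9) == "C", "-", "+"),
                    rep_name = get(10),
                    rep_class = sub("/.*$", "", cls),
                    rep_family = fam,
                    stringsAsFactors = FALSE)
  }
  x$rep_class <- .map_rep_class(x$rep_class)
  validate_intervals(x, where = paste0("rmsk ", path))
  x
}

#' Write a repeat table (UCSC rmsk-style TSV)
#'
#' @param repeats Repeat table from [read_rmsk()].
#' @param path Output path.
#' @export
write_rmsk <- function(repeats, path) {
  dt <- data.table::data.table(genoName = repeats$chrom,
                               genoStart = repeats$start,
                               genoEnd = repeats$end,
                               strand = repeats$strand,
                               repName = repeats$rep_name,
                               repClass = repeats$rep_class,
                               repFamily = repeats$rep_family)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tx_start`,
#' `tx_end`, `exon_starts`, `exon_ends` (comma-separated lists, BED-style
#' 0-based half-open).
#'
#' @param path Path to the table.
#' @return `data.frame` with the columns above (`exon_starts`/`exon_ends`
#'   remain comma strings; use [gene_first_exon()] / [gene_exons()] for
#'   interval views).
#' @export
read_gene_models <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = c("gene_id", "chrom",
                                                          "strand",
                                                          "exon_starts",
                                                          "exon_ends")))
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("gene-model table missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(dt)[, need]
  x$tx_start <- as.integer(x$tx_start); x$tx_end <- as.integer(x$tx_end)
  validate_gene_models(x)
  x
}

validate_gene_models <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (!all(genes$tx_start >= 0 & genes$tx_start < genes$tx_end))
    stop("gene models: need 0 <= tx_start < tx_end")
  ex <- gene_exons(genes)
  for (g in split(ex, ex$gene_id)) {
    if (is.unsorted(g$start, strictly = FALSE) ||
        any(g$start[-1] < g$end[-nrow(g)]))
      stop("gene ", g$gene_id[1], ": exons must be sorted and non-overlapping")
  }
  gl <- genes[match(ex$gene_id, genes$gene_id), ]
  if (any(ex$start < gl$tx_start | ex$end > gl$tx_end))
    stop("gene models: exon outside [tx_start, tx_end)")
  invisible(genes)
}

#' Write a gene-model table
#' @param genes Gene-model `data.frame`.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  data.table::fwrite(data.table::as.data.table(
    genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
              "exon_starts", "exon_ends")]),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Exon and first-exon interval views of a gene model
#'
#' The first exon is the 5'-most exon in transcription order: the leftmost
#' exon on `+`, the rightmost on `-`. The TSS is `tx_start` on `+` and
#' `tx_end - 1` on `-`.
#'
#' @param genes Gene-model `data.frame` (see [read_gene_models()]).
#' @return Interval `data.frame` with a `gene_id` column; `gene_exons()`
#'   returns one row per exon, `gene_first_exon()` one row per gene,
#'   `gene_tss()` the single-base TSS interval.
#' @export
gene_exons <- function(genes) {
  st <- strsplit(genes$exon_starts, ",")
  en <- strsplit(genes$exon_ends, ",")
  n <- lengths(st)
  if (!all(n == lengths(en))) stop("exon_starts/exon_ends length mismatch")
  if (any(n == 0)) {
    warning(sum(n == 0), " gene(s) without exons skipped")
  }
  data.frame(gene_id = rep(genes$gene_id, n),
             chrom = rep(genes$chrom, n),
             start = as.integer(unlist(st)),
             end = as.integer(unlist(en)),
             strand = rep(genes$strand, n),
             stringsAsFactors = FALSE)
}

#' @rdname gene_exons
#' @export
gene_first_exon <- function(genes) {
  ex <- gene_exons(genes)
  out <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    if (g$strand[1] == "+") g[which.min(g$start), ] else g[which.max(g$start), ]
  }))
  out <- out[match(intersect(genes$gene_id, out$gene_id), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' @rdname gene_exons
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pos, end = pos + 1L, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated; first column gene id, remaining columns one per sample
#' (header row required). Values must be complete, numeric and nonnegative.
#'
#' @param path Path to the table.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("expression table: duplicate gene id '",
         ids[duplicated(ids)][1], "'")
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("expression table: duplicate sample id")
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("expression table: non-numeric or missing cell at gene '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  if (any(m < 0))
    stop("expression table: negative value(s)")
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#' @param mat Gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Merge the two strands of each CpG dyad
#'
#' Sums methylated/unmethylated counts of the `+`-strand cytosine at
#' position `p` with the `-`-strand cytosine at `p + 1`. Only CpG-context
#' sites are merged; other contexts pass through unchanged. Merged sites
#' are reported at the `+`-strand position with strand `"+"`.
#'
#' @param sites Site table.
#' @return Site table with CpG dyads collapsed.
#' @export
merge_dyads <- function(sites) {
  cpg <- sites[sites$context == "CpG", , drop = FALSE]
  rest <- sites[sites$context != "CpG", , drop = FALSE]
  if (!nrow(cpg)) return(sites)
  # dyad anchor: + site at p pairs with - site at p+1
  anchor <- ifelse(cpg$strand == "+", cpg$pos, cpg$pos - 1L)
  dt <- data.table::data.table(chrom = cpg$chrom, pos = anchor,
                               n_meth = cpg$n_meth, n_unmeth = cpg$n_unmeth)
  agg <- dt[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
            by = list(chrom, pos)]
  merged <- data.frame(chrom = agg$chrom, pos = agg$pos, strand = "+",
                       context = "CpG", n_meth = agg$n_meth,
                       n_unmeth = agg$n_unmeth, stringsAsFactors = FALSE)
  out <- rbind(merged, rest[, names(merged)])
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
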