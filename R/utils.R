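#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n row_number across
#'   rename pull slice if_else first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom rlnorm rgeom median quantile sd var
#'   p.adjust pf pt qnorm setNames aggregate complete.cases
NULL

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, without
# disturbing the caller's RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single number or NULL.")
    }
    withr::with_seed(as.integer(seed), force(expr))
  }
}

# Derive a reproducible child seed from a global seed and a stage label,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 2654435L + as.integer(h %% 100000L)) %% 2147483647L
}

check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("Invalid strand value(s): %s (must be '+' or '-').",
                  paste(unique(strand[bad]), collapse = ", ")))
  }
  invisible(strand)
}

# Tibble of 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(df) {
  check_strand(df$strand)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

# Crosslink-site tibble (chrom, pos, strand) -> width-1 GRanges.
sites_to_granges <- function(df) {
  check_strand(df$strand)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos + 1L, width = 1L),
    strand = df$strand
  )
}

empty_track <- function() {
  tibble(chrom = character(), pos = integer(), strand = character(),
         count = integer())
}

empty_peaks <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), score = numeric(), fdr = numeric(),
         gene_id = character())
}

validate_track <- function(track) {
  req <- c("chrom", "pos", "strand", "count")
  missing_cols <- setdiff(req, names(track))
  if (length(missing_cols)) {
    abort(sprintf("Crosslink track is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  check_strand(track$strand)
  if (!is.numeric(track$pos) || any(track$pos != trunc(track$pos))) {
    abort("Crosslink positions must be whole numbers.")
  }
  if (any(track$count < 1)) abort("Crosslink counts must be >= 1.")
  invisible(track)
}
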