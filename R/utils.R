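## Internal helpers shared across modules.

## One megabase in bp; Mb-denominated user parameters are converted once.
.MB <- 1e6

## Chromosome-name normalization: "chr1" and "1" compare equal. Output keeps
## the input's convention; only comparisons go through this map.
.normChrom <- function(x) sub("^chr", "", as.character(x))

## Return a copy of a GRanges with normalized seqlevels, for cross-set
## interval arithmetic between objects that may use different naming styles.
.normSeqlevels <- function(gr) {
  if (length(gr) == 0L) {
    GenomeInfoDb::seqlevels(gr) <- character(0)
    return(gr)
  }
  map <- .normChrom(GenomeInfoDb::seqlevels(gr))
  ## styles can collide after stripping (e.g. "chr1" and "1" both present);
  ## collapse them onto one level
  gr2 <- GenomicRanges::GRanges(
    seqnames = .normChrom(as.character(GenomicRanges::seqnames(gr))),
    ranges = GenomicRanges::ranges(gr)
  )
  S4Vectors::mcols(gr2) <- S4Vectors::mcols(gr)
  gr2
}

## Put two GRanges on a shared, normalized seqlevel universe so that
## intersect/setdiff do not warn about disjoint seqinfo.
.onCommonSeqlevels <- function(a, b) {
  a <- .normSeqlevels(a)
  b <- .normSeqlevels(b)
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

## Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Sort a GRanges by (chromosome, start) with natural chromosome ordering.
.sortGR <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr)
}

.stopFatal <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "autozyg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
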