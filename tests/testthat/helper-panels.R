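# deterministic toy panels built in code

# panel from explicit haplotype rows (one string per haplotype, e.g. "010")
panel_from_strings <- function(rows, ids = NULL, allow_monomorphic = FALSE) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  ids <- ids %||% paste0("v", seq_len(ncol(m)))
  colnames(m) <- ids
  haplotype_panel(m, data.frame(id = ids, stringsAsFactors = FALSE),
                  allow_monomorphic = allow_monomorphic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small panel: N individuals, M variants, every column polymorphic
random_small_panel <- function(N, M, seed) {
  set.seed(seed)
  repeat {
    h <- matrix(rbinom(2 * N * M, 1L, runif(M, 0.15, 0.6)[rep(seq_len(M),
                                                              each = 2 * N)]),
                nrow = 2 * N)
    f <- colMeans(h)
    if (all(f > 0 & f < 1)) break
  }
  colnames(h) <- paste0("v", seq_len(M))
  haplotype_panel(h, data.frame(id = colnames(h), stringsAsFactors = FALSE))
}

# a small phased VCF written as text; `gts` is a list of per-site GT vectors
write_toy_vcf <- function(path, gts, pos = NULL, ref = "A", alt = "T",
                          ids = NULL) {
  n_samp <- length(gts[[1L]])
  pos <- pos %||% (100L + seq_along(gts))
  ids <- ids %||% rep(".", length(gts))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("S", seq_len(n_samp))),
                    collapse = "\t"))
  body <- vapply(seq_along(gts), function(i) {
    paste(c("19", pos[i], ids[i], ref, alt, ".", "PASS", ".", "GT",
            gts[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

# shared fixture for the heavier statistical tests
apoe_panel <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- synth_panel(apoe_like_config(), 1092,
                                                seed = 7)
    cached
  }
})
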