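# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Two-chromosome genome (2^17 bp each) with one planted boundary, a loop,
# open bins, a planted homology, and RNA-DNA pairs with truth table.
small_world <- function() memo("small_world", function() {
  cs <- stats::setNames(rep(2^17L, 2L), c("chr1", "chr2"))
  st <- plant_structure(
    cs,
    boundaries = data.frame(chrom = "chr1", pos = 20L * 2048L,
                            strength = 1.5, n_motifs = 2L),
    loops = data.frame(chrom = "chr2", posA = 10L * 2048L,
                       posB = 40L * 2048L, intensity = 8),
    open_bins = data.frame(chrom = rep(c("chr1", "chr2"), each = 8L),
                           bin = rep(seq(4L, 32L, by = 4L), 2L)))
  spec <- synthetic_genome_spec(n_chroms = 2L, chrom_length = 2^17L,
                                seed = 42L)
  genome <- make_genome(spec, structure = st)
  ids <- S4Vectors::mcols(genome$genes)$gene_id
  types <- S4Vectors::mcols(genome$genes)$gene_type
  lnc <- ids[types == "lncRNA"][1]
  genome <- plant_homologies(genome, list(
    planted_homology(lnc, "chr2", 90000L, identity = 0.9,
                     max_perfect_run = 15L, length = 100L)))
  expr <- stats::setNames(rep(600L, length(ids)), ids)
  cspec <- synthetic_contact_spec(expression = expr, cis_fraction = 0.6,
                                  intergenic_reads = 400L)
  rd <- make_rna_dna_pairs(cspec, genome, seed = 7L)
  dd <- make_dna_dna_pairs(st, depth = 6e4, seed = 8L)
  grid <- bin_grid(cs)
  list(chromsizes = cs, structure = st, genome = genome, rd = rd, dd = dd,
       grid = grid, lnc = lnc)
})

small_contacts <- function() memo("small_contacts", function() {
  w <- small_world()
  parse_rna_dna_pairs(list(records = w$rd$records,
                           chromsizes = w$chromsizes))
})

small_targets <- function() memo("small_targets", function() {
  w <- small_world()
  windows <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 2^17L)
  prepare_target_maps(w$dd, w$grid, windows)
})

# Constructed RNA/DNA string pairs where the optimal local alignment is the
# full-length ungapped alignment (ends anchored by matches, mutations
# isolated singletons), so identity and longest run can be read directly
# off the strings — an oracle independent of the aligner.
make_string_pair <- function(len, mut_positions, seed) {
  with_seed(seed, {
    rna <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    dna <- rna
    swap <- c(A = "C", C = "A", G = "T", T = "G")
    dna[mut_positions] <- swap[dna[mut_positions]]
    list(rna = paste(rna, collapse = ""), dna = paste(dna, collapse = ""),
         identity = 1 - length(mut_positions) / len,
         max_run = {
           m <- rep(TRUE, len); m[mut_positions] <- FALSE
           r <- rle(m); max(c(0, r$lengths[r$values]))
         })
  })
}

unclass_m <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

# with_seed equivalent for test code (mirrors the package-internal helper)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
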