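test_that("universal genetic code has the expected structure", {
  gc <- genetic_code()
  expect_length(gc$codons, 61)
  expect_setequal(gc$stops, c("TAA", "TAG", "TGA"))
  nb <- gc$neighbors
  # every neighbor pair differs at exactly one position
  from <- gc$codons[nb[, "from"]]
  to <- gc$codons[nb[, "to"]]
  ndiff <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), from, to)
  expect_true(all(ndiff == 1))
  # synonymous flag agrees with amino-acid identity
  expect_identical(as.integer(gc$aa[nb[, "from"]] == gc$aa[nb[, "to"]]),
                   as.integer(nb[, "syn"]))
  # the changed position and target nucleotide are recorded correctly
  pos_char <- substr(to, nb[, "pos"], nb[, "pos"])
  expect_identical(pos_char, gc$nt[nb[, "target_nt"]])
})

test_that("codon FASTA reading tokenizes, validates, and flags stops", {
  f <- write_fasta_tmp(c(">A", "ATGAAA", ">B", "ATGAAG"))
  aln <- read_codon_fasta(f)
  expect_equal(aln$n_sites, 2)
  expect_identical(aln$triplets[, 2], c(A = "AAA", B = "AAG")[aln$taxa])
  expect_equal(aln$states[, 1], rep(match("ATG", aln$code$codons), 2),
               ignore_attr = TRUE)

  f2 <- write_fasta_tmp(c(">A", "ATGTAA", ">B", "ATGAAG"))
  expect_error(read_codon_fasta(f2), "stop codon.*'A'.*column 2")

  f3 <- write_fasta_tmp(c(">A", "ATGAAA", ">A", "ATGAAG"))
  expect_error(read_codon_fasta(f3), "duplicate")

  f4 <- write_fasta_tmp(c(">A", "ATGAA", ">B", "ATGAA"))
  expect_error(read_codon_fasta(f4), "multiple of 3")

  f5 <- write_fasta_tmp(c(">A", "ATGAAA", ">B", "ATG"))
  expect_error(read_codon_fasta(f5), "lengths differ")
})

test_that("gap and ambiguity triplets are equivalent missing data", {
  # "A-G" and "NNN" must contribute exactly like "---" to the likelihood
  make <- function(trip) {
    codon_alignment(c(A = paste0("ATG", trip), B = "ATGAAG"))
  }
  a_gap <- make("---")
  a_mix <- make("A-G")
  a_amb <- make("NNN")
  expect_identical(a_gap$states, a_mix$states)
  phy <- read_newick("(A:0.1,B:0.2);", a_gap)
  dist <- list(omega = list(rates = 0.5, weights = 1),
               alpha = list(rates = 1, weights = 1))
  hy <- model_hyper(n_omega = 1, m_alpha = 1, error_sink = FALSE)
  ll <- vapply(list(a_gap, a_mix, a_amb), function(a)
    log_likelihood(busted_model(a, phy, fix_theta(), fix_pi(), dist, hy)),
    numeric(1))
  expect_equal(ll[2], ll[1], tolerance = 1e-12)
  expect_equal(ll[3], ll[1], tolerance = 1e-12)
})

test_that("read -> write round trip is lossless; masking writes gaps", {
  f <- write_fasta_tmp(c(">A", "ATGAAACCC", ">B", "ATGAAGCCA",
                         ">C", "ATG---CCG"))
  aln <- read_codon_fasta(f)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_masked_fasta(aln, out)
  expect_identical(read_codon_fasta(out)$triplets, aln$triplets)

  write_masked_fasta(aln, out, mask = data.frame(taxon = "A", site = 2))
  re <- read_codon_fasta(out)
  expect_identical(unname(re$triplets[re$taxa == "A", 2]), "---")
  expect_identical(re$triplets[re$taxa == "B", ], aln$triplets[aln$taxa == "B", ])

  # whole-column mask gaps every taxon
  whole <- expand.grid(taxon = aln$taxa, site = 3, stringsAsFactors = FALSE)
  write_masked_fasta(aln, out, mask = whole)
  re2 <- read_codon_fasta(out)
  expect_true(all(re2$triplets[, 3] == "---"))

  expect_error(write_masked_fasta(aln, out,
                                  mask = data.frame(taxon = "Z", site = 1)),
               "unknown taxa")
  expect_error(write_masked_fasta(aln, out,
                                  mask = data.frame(taxon = "A", site = 9)),
               "columns outside")
})

test_that("newick reading validates labels and branch lengths", {
  aln <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGAAC"))
  phy <- read_newick("((A:0.1,B:0.1):0.05,C:0.2);", aln)
  expect_equal(phy$ntip, 3)
  # a rooted 3-taxon tree collapses to the unrooted star; the branch to C
  # carries the {A,B} | {C} bipartition (its length absorbs the old
  # root segment), and every split partitions the full leaf set
  expect_equal(nrow(phy$edge), 3)
  ec <- which(phy$edge[, 2] == which(phy$phy$tip.label == "C"))
  expect_equal(phy$elen[ec], 0.25, tolerance = 1e-12)
  expect_setequal(phy$splits[[ec]]$inside, "C")
  expect_setequal(phy$splits[[ec]]$outside, c("A", "B"))

  expect_error(read_newick("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.2);", aln),
               "only in tree: D")
  expect_error(read_newick("((A:0.1,B:-0.1):0.05,C:0.2);", aln), "negative")

  # missing branch lengths default to a small positive value
  phy2 <- read_newick("((A,B),C);", aln)
  expect_true(all(phy2$elen > 0))
})

test_that("splits agree with independent bipartition enumeration", {
  withr::with_seed(7, {
    for (n in 4:6) {
      tr <- ape::rtree(n)
      tr$tip.label <- LETTERS[1:n]
      aln <- codon_alignment(stats::setNames(rep("ATGAAA", n), LETTERS[1:n]))
      phy <- phylogeny(tr, aln)
      pp <- ape::prop.part(tr)
      labs <- attr(pp, "labels")
      pp_sets <- lapply(pp, function(i) sort(labs[i]))
      for (e in seq_len(nrow(phy$edge))) {
        ch <- phy$edge[e, 2]
        inside <- sort(phy$splits[[e]]$inside)
        expect_setequal(c(phy$splits[[e]]$inside, phy$splits[[e]]$outside),
                        LETTERS[1:n])
        if (ch > phy$ntip) {
          expect_true(any(vapply(pp_sets, identical, logical(1), y = inside)))
        } else {
          expect_identical(inside, tr$tip.label[ch])
        }
      }
    }
  })
})
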