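# RBS inference rules, ORF preparation, overlap resolution, and the
# compile/parse round trip.

test_that("RBS inference applies the three 5'UTR rules", {
  genome <- strrep("ACGT", 200)  # 800 bp

  # (a) known TSS, UTR >= 15 bp: fragment from +1 to start-1
  part_a <- infer_rbs(tss = 101, start_codon = 161, genome)
  expect_identical(part_a$seq, substr(genome, 101, 160))
  expect_identical(nchar(part_a$seq), 60L)

  # (b) unknown TSS: the 60 bp upstream of the start codon
  part_b <- infer_rbs(tss = NA, start_codon = 500, genome)
  expect_identical(part_b$seq, substr(genome, 440, 499))
  expect_identical(nchar(part_b$seq), 60L)

  # (c) known TSS, UTR < 15 bp: UTR plus an additional 60 bp
  part_c <- infer_rbs(tss = 491, start_codon = 500, genome)
  expect_identical(nchar(part_c$seq), 9L + 60L)
  expect_identical(part_c$seq, substr(genome, 431, 499))

  # exactly 15 bp of UTR falls under rule (a)
  part_d <- infer_rbs(tss = 485, start_codon = 500, genome)
  expect_identical(nchar(part_d$seq), 15L)

  # contig edge with unknown TSS errors
  expect_error(infer_rbs(tss = NA, start_codon = 30, genome), "edge")
})

test_that("ORF preparation appends TAA systematically", {
  expect_identical(prepare_orf("ATGAAA")$seq, "ATGAAATAA")
  # appended even when the ORF already ends in a stop
  expect_identical(prepare_orf("ATGTAA")$seq, "ATGTAATAA")
  expect_error(prepare_orf(""), "non-empty")
  expect_error(prepare_orf("ATGNNN"), "non-ACGT")
  expect_warning(prepare_orf("ATGA"), "divisible")
})

test_that("opposite-strand overlaps are duplicated into both operons", {
  shared <- "GGGGCCCCAAAA"  # 12 bp
  seq_a <- paste0("ATGTTTTTT", shared)
  seq_b <- paste0(revcomp(shared), "ATGCCCCCC")
  op_a <- list(id = "opA", strand = "+", seq = seq_a,
               orf_seqs = "ATGTTTTTT")
  op_b <- list(id = "opB", strand = "-", seq = seq_b,
               orf_seqs = "ATGCCCCCC")
  out <- resolve_overlap(op_a, op_b, shared)
  expect_identical(attr(out, "duplicated_bp"), 12L)
  expect_true(grepl(shared, out$parts_a$seq, fixed = TRUE))
  expect_true(grepl(revcomp(shared), out$parts_b$seq, fixed = TRUE))
  expect_identical(nchar(out$parts_a$seq) + nchar(out$parts_b$seq),
                   (nchar(seq_a) + nchar(seq_b) - 12L) + 12L)

  # zero overlap: identity
  out0 <- resolve_overlap(op_a, op_b, "")
  expect_identical(attr(out0, "duplicated_bp"), 0L)
  expect_identical(out0$parts_a$seq, seq_a)

  # same-strand overlap out of scope
  op_b_plus <- op_b; op_b_plus$strand <- "+"
  expect_error(resolve_overlap(op_a, op_b_plus, shared), "opposite")

  # overlap swallowing an entire ORF is not a small portion
  op_small <- list(id = "opC", strand = "-",
                   seq = paste0(revcomp(paste0("ATGTTT", shared)), "AAA"),
                   orf_seqs = "ATGTTT")
  expect_error(
    resolve_overlap(list(id = "opA2", strand = "+",
                         seq = paste0("ATGTTT", shared),
                         orf_seqs = "ATGTTT"),
                    op_small, paste0("ATGTTT", shared)),
    "entire ORF")
})

test_that("arriving genes share one destination RBS; natives keep theirs", {
  w <- small_world(n_genes = 8, seed = 13)
  g <- w$g
  dest <- names(g$operons)[[1]]
  p1 <- assign_rbs(g, dest, "gX", "first_orf_rbs")
  p2 <- assign_rbs(g, dest, "gY", "first_orf_rbs")
  expect_identical(p1$seq, p2$seq)
  first_gene <- g$operons[[dest]]$genes[[1]]
  expect_identical(p1$seq,
                   unname(g$sequence_store[[
                     g$genes[[first_gene]]$native_rbs_ref]]))

  cfg <- compile_config(rbs_policy = "standard_rbs",
                        standard_rbs = "AGGAGGTAAAAAGGAGGTAA")
  p3 <- assign_rbs(g, dest, "gX", "standard_rbs", cfg)
  expect_identical(p3$seq, "AGGAGGTAAAAAGGAGGTAA")
})

test_that("compile/parse is an exact round trip and compile is deterministic", {
  for (seed in c(2, 9, 17)) {
    w <- small_world(n_genes = 10, seed = seed,
                     tandem_candidate_fraction = 0.3)
    g <- w$g
    cg <- compile_gtrn(g)
    expect_true(gtrn_equal(g, parse_genome(cg)))
    cg2 <- compile_gtrn(g)
    expect_identical(cg$sequence, cg2$sequence)
    expect_identical(cg, cg2)
  }
})

test_that("round trip survives refactoring moves and GenBank serialization", {
  w <- small_world(n_genes = 12, seed = 31, tandem_candidate_fraction = 0.4)
  g <- w$g
  sch <- annealing_schedule(population = 1, seed = 1)
  set.seed(77)
  for (i in 1:25) g <- propose(g, sch)$gtrn
  cg <- compile_gtrn(g)
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(cg, path)
  g2 <- parse_genome(path)
  expect_true(gtrn_equal(g, g2))
  # compile . parse . compile is byte-identical
  path2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(compile_gtrn(g2), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("every ORF appears exactly once in a compiled genome", {
  w <- small_world(n_genes = 10, seed = 41)
  g <- w$g
  set.seed(3)
  sch <- annealing_schedule(population = 1, seed = 1)
  for (i in 1:15) g <- propose(g, sch)$gtrn
  cg <- compile_gtrn(g)
  for (gn in g$genes) {
    orf <- g$sequence_store[[gn$orf_seq_ref]]
    oid <- operon_of(g, gn$id)
    target <- if (g$operons[[oid]]$strand == "-") revcomp(orf) else orf
    hits <- gregexpr(target, cg$sequence, fixed = TRUE)[[1]]
    expect_identical(sum(hits > 0), 1L)
  }
})

test_that("moved genes compile as last cistron with the destination RBS", {
  w <- small_world(n_genes = 8, seed = 23)
  g <- w$g
  ops <- gtrnr:::.nonconstitutive_operons(g)
  skip_if(length(ops) < 2)
  gid <- g$operons[[ops[1]]]$genes[[1]]
  g2 <- move_gene(g, gid, ops[2])$gtrn
  cg <- compile_gtrn(g2)
  # the moved CDS is the last CDS of the destination operon
  cds <- Filter(function(f) f$type == "CDS" &&
                  identical(f$qualifiers$operon_id, ops[2]), cg$features)
  dest_op <- g2$operons[[ops[2]]]
  ord <- order(vapply(cds, `[[`, 0L, "start"))
  if (dest_op$strand == "-") ord <- rev(ord)
  expect_identical(cds[[ord[length(ord)]]]$qualifiers$gene, gid)
  # and its RBS is the assigned (destination) one
  rbs <- Filter(function(f) f$type == "RBS" &&
                  identical(f$qualifiers$gene, gid), cg$features)
  expect_identical(rbs[[1]]$qualifiers$source, "assigned")
})

test_that("tandem promoters appear as stacked regions with spacers", {
  w <- small_world(n_genes = 8, seed = 5, tandem_candidate_fraction = 0.5)
  g <- w$g
  oid <- names(g$operons)[[1]]
  cands <- setdiff(g$tandem_candidates, g$operons[[oid]]$primary_promoter)
  skip_if(length(cands) < 2)
  g <- add_tandem(g, oid, cands[1])$gtrn
  g <- add_tandem(g, oid, cands[2])$gtrn
  cg <- compile_gtrn(g)
  fs <- Filter(function(f) identical(f$qualifiers$operon_id, oid),
               cg$features)
  types <- vapply(fs, `[[`, "", "type")
  proms <- Filter(function(f) f$type == "promoter", fs)
  expect_identical(length(proms), 3L)
  # 3 promoter regions, 2 isolation spacers, all upstream of the first RBS
  expect_identical(sum(types == "spacer"), 2L)
  strand <- fs[[1]]$strand
  prom_pos <- vapply(proms, `[[`, 0L, "start")
  rbs_pos <- vapply(Filter(function(f) f$type == "RBS", fs), `[[`, 0L,
                    "start")
  if (strand == "+") expect_true(max(prom_pos) < min(rbs_pos))
  else expect_true(min(prom_pos) > max(rbs_pos))
})

test_that("missing parts and truncated files produce hard errors", {
  g <- single_gene_gtrn()
  g$sequence_store <- g$sequence_store[names(g$sequence_store) != "orf_g1"]
  expect_error(compile_gtrn(g), "orf_g1")

  w <- small_world(n_genes = 6, seed = 2)
  cg <- compile_gtrn(w$g)
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(cg, path)
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 10)], path)
  expect_error(parse_genome(path), "truncated")
})
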