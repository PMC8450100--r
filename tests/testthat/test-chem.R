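# Bioactivity filtering, the iterative pChEMBL pool search, fingerprint
# similarity, clustering and diverse selection.

# Crafted bioactivity datastore: one record per compound at a chosen
# pChEMBL value against a chosen target.
make_bioactivity_ds <- function(pchembl, targets = "P01",
                                taxa = 9606L) {
  dir <- tempfile("chem-ds-")
  dir.create(dir)
  n <- length(pchembl)
  cid <- sprintf("X%03d", seq_len(n))
  tgt <- rep_len(targets, n)
  prot <- unique(tgt)
  writeLines(c("protein_id\tgene_symbol\ttaxon_id\treviewed\tdisease_ids\tpathway_ids\tphenotype_ids",
               sprintf("%s\tG%s\t%d\ttrue\t\t\t", prot, prot, taxa)),
             file.path(dir, "proteins.tsv"))
  writeLines("protein_a\tprotein_b\tconfidence", file.path(dir, "ppis.tsv"))
  writeLines("term_id\tcomponent\tname\tsource\tparent_ids\tpathway_ids\tphenotype_ids",
             file.path(dir, "terms.tsv"))
  writeLines("drug_id\tname\tstatus\ttarget_protein_ids\tindication_disease_ids\tcompound_xref",
             file.path(dir, "drugs.tsv"))
  writeLines(c("compound_id\tname\tfingerprint\tfp_width",
               sprintf("%s\tcpd %s\t%d,%d\t64", cid, cid,
                       seq_len(n) %% 60, (seq_len(n) %% 60) + 1L)),
             file.path(dir, "compounds.tsv"))
  writeLines(c("compound_id\ttarget_protein_id\tstandard_type\tpchembl\ttarget_kind\ttaxon_id",
               sprintf("%s\t%s\tIC50\t%s\tsingle_protein\t%d", cid, tgt,
                       format(pchembl, trim = TRUE), taxa)),
             file.path(dir, "bioactivities.tsv"))
  writeLines("compound_or_drug_id\ttarget_protein_id\tsource_model\tscore",
             file.path(dir, "predicted_dtis.tsv"))
  jsonlite::write_json(
    list(proteins = "proteins.tsv", ppis = "ppis.tsv", terms = "terms.tsv",
         drugs = "drugs.tsv", compounds = "compounds.tsv",
         bioactivities = "bioactivities.tsv",
         predicted_dtis = "predicted_dtis.tsv"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  load_datastore(file.path(dir, "manifest.json"), strict = TRUE)
}

test_that("concentrations convert to the pChEMBL scale", {
  expect_identical(pchembl_from_concentration(10, "uM"), 5)  # 10 uM <-> 5
  expect_identical(pchembl_from_concentration(10, "µM"), 5)
  expect_equal(pchembl_from_concentration(1, "nM"), 9)
  expect_equal(pchembl_from_concentration(1, "M"), 0)
  expect_error(pchembl_from_concentration(0, "uM"), "> 0")
})

test_that("tanimoto is the on-bit Jaccard coefficient", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(7, 9), c(7, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_error(tanimoto(integer(0), integer(0)), "undefined")
  set.seed(5)
  for (i in 1:20) {
    a <- random_fp(); b <- random_fp()
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_true(tanimoto(a, b) >= 0 && tanimoto(a, b) <= 1)
  }
})

test_that("leader clustering groups similar fingerprints deterministically", {
  near <- list(a = c(1:8), b = c(1:7, 9), c = c(1:6, 10, 11))
  expect_equal(length(cluster_compounds(near)$representatives), 1L)
  far <- list(a = 1:8, b = 21:28, c = 41:48)
  expect_equal(length(cluster_compounds(far)$representatives), 3L)
  # permutation invariance of the full assignment
  set.seed(9)
  fps <- lapply(1:30, function(i) random_fp(64, 10))
  names(fps) <- sprintf("C%02d", 1:30)
  c1 <- cluster_compounds(fps)
  c2 <- cluster_compounds(fps[sample(30)])
  expect_equal(c1$assignment[sort(names(c1$assignment))],
               c2$assignment[sort(names(c2$assignment))])
  # member-to-representative similarity honours the threshold
  reps <- c1$representatives
  for (id in names(fps)) {
    r <- reps[c1$assignment[[id]]]
    expect_gte(tanimoto(fps[[id]], fps[[r]]), 0.5)
  }
  # empty input and empty fingerprints
  expect_length(cluster_compounds(list())$assignment, 0L)
  expect_error(cluster_compounds(list(a = integer(0))), "empty fingerprint")
})

test_that("planted scaffold clusters are recovered at the 0.5 threshold", {
  ds <- synth_datastore(synth_params(n_compounds = 30L,
                                     n_scaffold_clusters = 3L,
                                     rng_seed = 21L))
  fps <- setNames(ds$compounds$fingerprint, ds$compounds$compound_id)
  cl <- cluster_compounds(fps, threshold = 0.5)
  expect_equal(length(cl$representatives), 3L)
  planted <- attr(ds, "ground_truth")$scaffold_clusters
  for (members in planted)
    expect_length(unique(cl$assignment[unlist(members)]), 1L)
  # independent oracle: connected components of the pairwise-similarity
  # graph at 0.5 give the same partition
  sl <- cluster_compounds(fps, threshold = 0.5, method = "single_linkage")
  expect_equal(length(sl$representatives), 3L)
  expect_equal(unname(sl$assignment[names(cl$assignment)]),
               unname(cl$assignment))
})

test_that("bioactivity filter keeps only comparable, confident records", {
  ds <- load_datastore(write_tiny_datastore(), strict = TRUE)
  kept <- filter_bioactivities(ds$bioactivities, taxa = 9606L,
                               pchembl_min = 5)
  # GI50 (off-type), missing pChEMBL and complex-target rows are out
  expect_false(any(toupper(kept$standard_type) == "GI50"))
  expect_false(any(is.na(kept$pchembl)))
  expect_true(all(kept$target_kind == "single_protein"))
  expect_equal(nrow(kept), 5L)  # manual recount of the fixture

  # recount oracle on random records
  set.seed(33)
  rec <- data.frame(
    compound_id = sprintf("C%03d", 1:100),
    target_protein_id = "P01",
    standard_type = sample(c("IC50", "ki", "GI50", "Potency"), 100, TRUE),
    pchembl = ifelse(runif(100) < 0.2, NA, runif(100, 3, 10)),
    target_kind = sample(c("single_protein", "complex"), 100, TRUE,
                         prob = c(0.8, 0.2)),
    taxon_id = sample(c(9606L, 10090L), 100, TRUE),
    stringsAsFactors = FALSE)
  kept <- filter_bioactivities(rec, taxa = 9606L, pchembl_min = 5)
  brute <- rec[rec$target_kind == "single_protein" &
               toupper(rec$standard_type) %in%
                 c("IC50", "KI", "POTENCY") &
               !is.na(rec$pchembl) & rec$pchembl >= 5 &
               rec$taxon_id == 9606L, ]
  expect_equal(nrow(kept), nrow(brute))
  expect_setequal(kept$compound_id, brute$compound_id)
})

test_that("the iterative cutoff search lands inside the pool bounds", {
  # 8 compounds at >= 8, of which 4 at >= 8.5; bounds 3..5 force one raise
  ds <- make_bioactivity_ds(c(rep(8.2, 4), rep(8.7, 4), rep(5.5, 6)))
  pool <- assemble_compound_pool(ds, "P01", lower = 3L, upper = 5L,
                                 start_cutoff = 8)
  expect_equal(pool$final_cutoff, 8.5)
  expect_equal(pool$iterations, 2L)
  expect_length(pool$distinct_compounds, 4L)
  expect_false(pool$floor_relaxed)

  # already in range: no adjustment
  pool <- assemble_compound_pool(ds, "P01", lower = 3L, upper = 10L,
                                 start_cutoff = 8)
  expect_equal(pool$final_cutoff, 8)
  expect_equal(pool$iterations, 1L)
  expect_length(pool$distinct_compounds, 8L)

  # too few even at the floor: accept the remainder, flag set
  ds2 <- make_bioactivity_ds(c(6.0, 6.5, 7.0))
  pool <- assemble_compound_pool(ds2, "P01", lower = 10L, upper = 20L,
                                 start_cutoff = 8, floor = 5)
  expect_equal(pool$final_cutoff, 5)
  expect_true(pool$floor_relaxed)
  expect_length(pool$distinct_compounds, 3L)

  # lowering direction finds the first admissible cutoff
  ds3 <- make_bioactivity_ds(runif(40, 5, 10))
  pool <- assemble_compound_pool(ds3, "P01", lower = 20L, upper = 35L,
                                 start_cutoff = 8)
  n <- length(pool$distinct_compounds)
  expect_true(n >= 20L && n <= 35L)
  expect_true(all(pool$records$pchembl >= pool$final_cutoff))

  # empty target set: empty pool, flagged, not an error
  expect_warning(pool <- assemble_compound_pool(ds, character(0)),
                 "empty target")
  expect_length(pool$distinct_compounds, 0L)
})

test_that("diverse selection never repeats a cluster and matches greedy", {
  mk_rank <- function(ids) {
    data.frame(term_id = ids, m = seq_along(ids), n = 10,
               M = seq_along(ids), N = 100,
               E = rev(seq_along(ids)), S = 0.5, stringsAsFactors = FALSE)
  }
  cl <- structure(list(assignment = c(c1 = 1L, c2 = 1L, c3 = 2L),
                       representatives = c("c1", "c3"),
                       threshold = 0.5, method = "leader"),
                  class = "kg_clusters")
  sel <- select_diverse_compounds(mk_rank(c("c1", "c2", "c3")), cl, 2)
  expect_equal(sel$term_id, c("c1", "c3"))  # same-cluster c2 skipped
  # all same cluster -> a single selection regardless of k
  cl1 <- structure(list(assignment = c(c1 = 1L, c2 = 1L, c3 = 1L),
                        representatives = "c1",
                        threshold = 0.5, method = "leader"),
                   class = "kg_clusters")
  expect_equal(nrow(select_diverse_compounds(mk_rank(c("c1", "c2", "c3")),
                                             cl1, 5)), 1L)
  # an already-present cluster is skipped outright
  sel <- select_diverse_compounds(mk_rank(c("c1", "c2", "c3")), cl, 2,
                                  already_present_clusters = 1L)
  expect_equal(sel$term_id, "c3")

  # random fixture vs an independent greedy oracle
  set.seed(14)
  ids <- sprintf("C%02d", 1:50)
  assign <- setNames(sample(1:10, 50, TRUE), ids)
  clr <- structure(list(assignment = assign,
                        representatives = ids[!duplicated(assign)],
                        threshold = 0.5, method = "leader"),
                   class = "kg_clusters")
  ranked <- mk_rank(ids)
  sel <- select_diverse_compounds(ranked, clr, 10)
  expect_lte(max(table(assign[sel$term_id])), 1L)
  greedy <- character(0); seen <- integer(0)
  for (id in ranked$term_id) {
    if (length(greedy) >= 10) break
    if (assign[[id]] %in% seen) next
    greedy <- c(greedy, id); seen <- c(seen, assign[[id]])
  }
  expect_equal(sel$term_id, greedy)
})
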