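# Shared fixtures, all built programmatically at test time.

# Write a hand-crafted tiny datastore and return the manifest path.
# Known truth: 50 proteins (40 human / 10 mouse, 5 of the human ones
# unreviewed), 3 diseases, 2 pathways, 2 phenotypes, 10 PPIs, 3 drugs,
# 4 compounds, 8 bioactivities, 4 predicted DTIs.
write_tiny_datastore <- function(dir = tempfile("tiny-ds-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(lines, name) writeLines(lines, file.path(dir, name))

  pid <- sprintf("P%02d", 1:50)
  taxon <- c(rep(9606L, 40), rep(10090L, 10))
  reviewed <- rep("true", 50); reviewed[36:40] <- "false"  # human unreviewed
  dis <- rep("", 50)
  dis[1:3] <- "D1"            # D1 annotates P01..P03
  dis[4:5] <- "D2"            # D2 annotates P04, P05
  dis[6] <- "D1|D3"           # P06 has two diseases
  pwy <- rep("", 50); pwy[1:4] <- "W1"; pwy[5:6] <- "W2"
  hpo <- rep("", 50); hpo[2:4] <- "H1"; hpo[7] <- "H2"
  w(c("protein_id\tgene_symbol\ttaxon_id\treviewed\tdisease_ids\tpathway_ids\tphenotype_ids",
      sprintf("%s\tG%02d\t%d\t%s\t%s\t%s\t%s", pid, 1:50, taxon, reviewed,
              dis, pwy, hpo)),
    "proteins.tsv")

  ppi <- c("P01\tP02\t0.9", "P01\tP03\t0.7", "P02\tP03\t0.55",
           "P03\tP04\t0.4", "P04\tP05\t0.8", "P05\tP06\t0.3",
           "P01\tP07\t0.65", "P02\tP07\t0.72", "P41\tP42\t0.95",
           "P01\tP41\t0.5")
  w(c("protein_a\tprotein_b\tconfidence", ppi), "ppis.tsv")

  w(c("term_id\tcomponent\tname\tsource\tparent_ids\tpathway_ids\tphenotype_ids",
      "D1\tdisease\talpha syndrome\tsynthetic\t\tW1\tH1",
      "D2\tdisease\tbeta syndrome\tsynthetic\t\t\t",
      "D3\tdisease\tgamma syndrome\tsynthetic\t\t\tH2",
      "W1\tpathway\tsignalling one\tsynthetic\t\t\t",
      "W2\tpathway\tsignalling two\tsynthetic\t\t\t",
      "H1\tphenotype\tpheno one\tsynthetic\t\t\t",
      "H2\tphenotype\tpheno two\tsynthetic\tH1\t\t"),
    "terms.tsv")

  w(c("drug_id\tname\tstatus\ttarget_protein_ids\tindication_disease_ids\tcompound_xref",
      "DRA\taladrug\tapproved\tP01|P02\tD1\tCA",
      "DRB\tbetadrug\tinvestigational\tP04|P41\tD2\t",
      "DRC\tgammadrug\tapproved\tP07\t\t"),
    "drugs.tsv")

  w(c("compound_id\tname\tfingerprint\tfp_width",
      "CA\tcompound A\t1,2,3,4\t64",
      "CB\tcompound B\t2,3,4,5\t64",
      "CC\tcompound C\t40,41,42,43\t64",
      "CD\tcompound D\t10,20,30\t64"),
    "compounds.tsv")

  w(c("compound_id\ttarget_protein_id\tstandard_type\tpchembl\ttarget_kind\ttaxon_id",
      "CA\tP01\tIC50\t7.1\tsingle_protein\t9606",
      "CA\tP02\tKi\t6.2\tsingle_protein\t9606",
      "CB\tP01\tIC50\t8.4\tsingle_protein\t9606",
      "CB\tP02\tEC50\t5.5\tsingle_protein\t9606",
      "CC\tP04\tIC50\t9.0\tsingle_protein\t9606",
      "CC\tP05\tGI50\t9.0\tsingle_protein\t9606",   # off-type
      "CD\tP06\tIC50\t\tsingle_protein\t9606",      # missing pChEMBL
      "CD\tP07\tKd\t6.6\tcomplex\t9606"),           # non-single target
    "bioactivities.tsv")

  w(c("compound_or_drug_id\ttarget_protein_id\tsource_model\tscore",
      "CD\tP01\tcnn-dti\t0.91",
      "CD\tP02\tcnn-dti\t0.85",
      "DRC\tP03\tpcm-dti\t0.77",
      "CB\tP05\tcnn-dti\t0.60"),
    "predicted_dtis.tsv")

  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(proteins = "proteins.tsv", ppis = "ppis.tsv", terms = "terms.tsv",
         drugs = "drugs.tsv", compounds = "compounds.tsv",
         bioactivities = "bioactivities.tsv",
         predicted_dtis = "predicted_dtis.tsv"),
    man, auto_unbox = TRUE)
  man
}

# A dirty variant exercising load-time cleanup: a self-loop PPI, a
# duplicate unordered pair with disagreeing confidence, and rows with
# unresolvable references.
write_dirty_datastore <- function(dir = tempfile("dirty-ds-")) {
  man <- write_tiny_datastore(dir)
  cat("P09\tP09\t0.8\n", file = file.path(dir, "ppis.tsv"), append = TRUE)
  cat("P02\tP01\t0.2\n", file = file.path(dir, "ppis.tsv"), append = TRUE)
  cat("P01\tPX9\t0.9\n", file = file.path(dir, "ppis.tsv"), append = TRUE)
  cat("CA\tPX9\tIC50\t7.0\tsingle_protein\t9606\n",
      file = file.path(dir, "bioactivities.tsv"), append = TRUE)
  man
}

# Session-cached synthetic datastore (defaults) so builder/analysis tests
# do not regenerate it per test file.
.fixture_cache <- new.env(parent = emptyenv())

cached_synth_ds <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- synth_datastore(synth_params(rng_seed = 11L))
  .fixture_cache$ds
}

cached_synth_view <- function() {
  if (is.null(.fixture_cache$view))
    .fixture_cache$view <- filter_proteins_by_taxon(cached_synth_ds(),
                                                    9606L, TRUE)
  .fixture_cache$view
}

# Random sparse fingerprint helper.
random_fp <- function(width = 128L, bits = 16L) {
  sort(sample(seq_len(width) - 1L, bits))
}
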