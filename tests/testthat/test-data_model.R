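test_that("feature matrices validate their domain and survive a round trip", {
  m <- feature_matrix(matrix(0L, 3, 2, dimnames = list(paste0("d", 1:3),
                                                       c("f1", "f2"))),
                      source_name = "chemical")
  expect_s3_class(m, "feature_matrix")
  expect_equal(sum(m), 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  m2 <- feature_matrix(rbind(d1 = c(a = 1, b = 0, c = 1),
                             d2 = c(1, 1, 0),
                             d3 = c(0, 0, 0)), source_name = "side_effect")
  write_incidence_matrix(m2, path)
  back <- load_feature_matrix(path, "side_effect")
  expect_identical(unclass(back), unclass(m2))

  bad <- matrix(c(0, 2, 1, 0), 2, 2,
                dimnames = list(c("d1", "d2"), c("f1", "f2")))
  expect_error(feature_matrix(bad), "non-binary cell.*row 'd2', column 'f1'")
  dup <- matrix(0, 2, 2, dimnames = list(c("d1", "d1"), c("f1", "f2")))
  expect_error(feature_matrix(dup), "duplicate drug id")
})

test_that("sparsity is the zero fraction and complements density exactly", {
  allones <- feature_matrix(matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                            c("x", "y"))))
  expect_identical(sparsity(allones), 0)
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rbinom(30, 1, runif(1)), 5, 6,
                dimnames = list(paste0("d", 1:5), paste0("f", 1:6)))
    expect_identical(sparsity(m) + sum(m) / length(m), 1)
  }
  expect_error(sparsity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("synonym harmonization merges aliases by OR and drops uncovered drugs", {
  chem <- feature_matrix(rbind(Ursodiol = c(1, 0), OtherDrug = c(0, 1)),
                         source_name = "chemical",
                         feature_ids = c("s1", "s2"))
  prot <- feature_matrix(rbind(`Ursodeoxycholic acid` = c(1, 0),
                               OtherDrug = c(0, 1)),
                         source_name = "protein", feature_ids = c("p1", "p2"))
  golden <- golden_associations(rbind(`Ursodeoxycholic acid` = c(1, 0),
                                      OtherDrug = c(0, 1),
                                      Orphan = c(1, 1)),
                                disease_ids = c("dis1", "dis2"))
  ds <- repo_dataset(list(chemical = chem, protein = prot), golden)
  syn <- synonym_map(c(Ursodiol = "Ursodeoxycholic acid"))
  h <- harmonize_names(ds, syn, quiet = TRUE)

  for (src in names(h$features))
    expect_true("Ursodeoxycholic acid" %in% rownames(h$features[[src]]))
  expect_false("Ursodiol" %in% rownames(h$features$chemical))
  # Orphan has no feature row anywhere and is dropped from the golden set
  expect_identical(sort(rownames(h$golden)),
                   c("OtherDrug", "Ursodeoxycholic acid"))
  expect_equal(attr(h, "harmonize_log")$dropped, 1L)

  # merging two records of the same canonical drug ORs their rows
  chem2 <- feature_matrix(rbind(A = c(1, 0), B = c(0, 1)),
                          source_name = "chemical",
                          feature_ids = c("s1", "s2"))
  g2 <- golden_associations(rbind(A = c(1, 0), B = c(0, 1)),
                            disease_ids = c("x", "y"))
  h2 <- harmonize_names(repo_dataset(list(chemical = chem2), g2),
                        synonym_map(c(B = "A")), quiet = TRUE)
  expect_equal(as.vector(h2$features$chemical["A", ]), c(1, 1))
  expect_equal(as.vector(h2$golden["A", ]), c(1, 1))
})

test_that("harmonization is idempotent and a no-op without synonyms", {
  ds <- toy_dataset()
  h0 <- harmonize_names(ds, NULL, quiet = TRUE)
  expect_identical(unclass(h0$golden), unclass(ds$golden))
  syn <- synonym_map(c(d2 = "d1"))
  h1 <- harmonize_names(ds, syn, quiet = TRUE)
  h2 <- harmonize_names(h1, syn, quiet = TRUE)
  expect_identical(h1$features, h2$features)
  expect_identical(unclass(h1$golden), unclass(h2$golden))
})

test_that("synonym chains collapse so one application suffices", {
  m <- synonym_map(c(a = "b", b = "c"))
  expect_identical(unname(unclass(m)[["a"]]), "c")
  expect_error(synonym_map(c(a = "b", b = "a")), "cycle")
})

test_that("sequence containers reject empty or out-of-alphabet residues", {
  expect_error(sequence_features(list(d1 = "")), "empty sequence")
  expect_error(sequence_features(list(d1 = "ACDEZ")),
               "residue 'Z' at position 5")
  sf <- sequence_features(list(d1 = c("ACDE", "GHIK")))
  expect_length(sf$d1, 2L)
})

test_that("sequence FASTA round trip groups sequences by drug", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  seqs <- load_sequence_features(file.path(dir, "sequences.fasta"))
  expect_setequal(names(seqs), names(ds$sequences))
  expect_identical(unname(seqs[["d3"]]), unname(ds$sequences[["d3"]]))
})
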