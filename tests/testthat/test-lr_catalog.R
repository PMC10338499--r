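test_that("loading a source deduplicates pairs and reports counts", {
  path <- write_lr_csv(tibble::tibble(
    ligand = c("TGFB1", "IL6", "TGFB1"),
    receptor = c("TGFBR1", "IL6R", "TGFBR1")
  ))
  cat <- load_lr_source(path, "srcA", "human")
  expect_s3_class(cat, "lr_catalog")
  expect_equal(nrow(cat), 2)
  rep <- attr(cat, "load_report")
  expect_equal(rep$n_rows, 3)
  expect_equal(rep$n_duplicates, 1)
})

test_that("column mapping, evidence parsing and id mapping work on load", {
  path <- write_lr_csv(tibble::tibble(
    from = c("TGFB1", "IL6"), to = c("TGFBR1", "IL6R"),
    support = c("curated", "computational")
  ))
  id_map <- tibble::tibble(symbol = c("TGFB1", "TGFBR1", "IL6"),
                           gene_id = c("ENSG1", "ENSG2", "ENSG3"))
  cat <- load_lr_source(path, "srcA", "human",
                        columns = list(ligand = "from", receptor = "to",
                                       evidence = "support"),
                        id_map = id_map)
  expect_setequal(cat$ligand, c("ENSG1", "ENSG3"))
  # IL6R missing from the map: keeps its symbol, flagged
  row <- cat[cat$ligand == "ENSG3", ]
  expect_equal(row$receptor, "IL6R")
  expect_true(row$id_flag)
  expect_equal(attr(cat, "load_report")$n_unmapped, 1)
  expect_equal(cat$evidence[cat$ligand == "ENSG1"], "manually_curated")
  expect_equal(cat$evidence[cat$ligand == "ENSG3"], "predicted")
})

test_that("a missing required column is a schema error naming the column", {
  path <- write_lr_csv(tibble::tibble(ligand = "TGFB1", other = "x"))
  expect_error(load_lr_source(path, "srcA", "human"), "receptor")
})

test_that("an empty source yields an empty catalog with a warning", {
  path <- write_lr_csv(tibble::tibble(ligand = character(),
                                      receptor = character()))
  expect_warning(cat <- load_lr_source(path, "srcA", "human"), "empty")
  expect_equal(nrow(cat), 0)
})

test_that("malformed rows with empty gene fields are dropped and counted", {
  path <- write_lr_csv(tibble::tibble(
    ligand = c("TGFB1", "", "IL6"), receptor = c("TGFBR1", "X", "IL6R")
  ))
  expect_message(cat <- load_lr_source(path, "srcA", "human"), "empty gene")
  expect_equal(nrow(cat), 2)
  expect_equal(attr(cat, "load_report")$n_malformed, 1)
})

test_that("merge unions pairs and accumulates sources", {
  a <- quick_catalog(c("L1", "L2", "L3"), c("R1", "R2", "R3"), src = "A")
  b <- quick_catalog(c("L3", "L4", "L5", "L6"), c("R3", "R4", "R5", "R6"),
                     src = "B")
  m <- merge_catalogs(list(a, b))
  expect_equal(nrow(m), 6) # 3 + 4 - 1 shared
  shared <- m[m$ligand == "L3", ]
  expect_equal(shared$sources, "A;B")
  expect_setequal(attr(m, "source_names"), c("A", "B"))
})

test_that("curated evidence in any source wins on merge", {
  a <- quick_catalog("L1", "R1", src = "A", evidence = "manually_curated")
  b <- quick_catalog("L1", "R1", src = "B", evidence = "predicted")
  m <- merge_catalogs(list(a, b))
  expect_equal(m$evidence, "manually_curated")
  # order must not matter
  m2 <- merge_catalogs(list(b, a))
  expect_equal(m2$evidence, "manually_curated")
})

test_that("mixed-species merge is refused", {
  a <- quick_catalog("L1", "R1", species = "human")
  b <- quick_catalog("L1", "R1", species = "mouse")
  expect_error(merge_catalogs(list(a, b)), "species")
})

test_that("merge is idempotent, commutative and associative on random catalogs", {
  set.seed(42)
  strip <- function(x) {
    a <- tibble::as_tibble(x)
    a[order(a$ligand, a$receptor), ]
  }
  for (i in 1:5) {
    a <- random_catalog(sample(5:30, 1), src = "A")
    b <- random_catalog(sample(5:30, 1), src = "B")
    c <- random_catalog(sample(5:30, 1), src = "C")
    ab <- merge_catalogs(list(a, b))
    expect_equal(strip(merge_catalogs(list(ab, b))), strip(ab))
    expect_equal(strip(ab), strip(merge_catalogs(list(b, a))))
    expect_equal(strip(merge_catalogs(list(ab, c))),
                 strip(merge_catalogs(list(a, merge_catalogs(list(b, c))))))
  }
})

test_that("ligand and receptor roles are directional", {
  a <- quick_catalog(c("A", "B"), c("B", "A"), src = "A")
  expect_equal(nrow(a), 2)
})

test_that("classification intersects ligand and receptor group annotations", {
  cat <- quick_catalog(c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  annot <- list(
    L1 = "chemokine", R1 = "chemokine",
    L2 = "cytokine", # R2 unannotated
    L3 = c("interleukin", "cytokine"), R3 = c("interleukin", "cytokine")
  )
  cl <- classify_pairs(cat, annot)
  got <- setNames(cl$primary_group, cl$ligand)
  expect_equal(got[["L1"]], "chemokine")
  expect_equal(got[["L2"]], "other")
  # interleukin precedes cytokine in the default priority
  expect_equal(got[["L3"]], "interleukin")
  expect_equal(cl$all_groups[cl$ligand == "L3"], "interleukin;cytokine")
})

test_that("a custom priority order decides multi-group pairs", {
  cat <- quick_catalog("L3", "R3")
  annot <- list(L3 = c("interleukin", "cytokine"),
                R3 = c("interleukin", "cytokine"))
  pri <- c("cytokine", setdiff(lr_groups(), "cytokine"))
  cl <- classify_pairs(cat, annot, priority = pri)
  expect_equal(cl$primary_group, "cytokine")
  expect_error(classify_pairs(cat, annot, priority = c("cytokine", "made up")),
               "permutation")
})

test_that("every pair gets exactly one primary group and is 'other' iff unmatched", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:40)
  annot <- lapply(setNames(genes, genes), function(g) {
    k <- sample(0:3, 1)
    if (k == 0) character() else sample(lr_groups(), k)
  })
  cat <- quick_catalog(sample(genes, 30, replace = FALSE),
                       sample(genes, 30, replace = FALSE))
  cl <- classify_pairs(cat, annot)
  expect_true(all(cl$primary_group %in% c(lr_groups(), "other")))
  expect_equal(cl$primary_group == "other", cl$all_groups == "")
  # invariance to annotation map order
  cl2 <- classify_pairs(cat, rev(annot))
  expect_equal(cl$primary_group, cl2$primary_group)
  expect_equal(cl$all_groups, cl2$all_groups)
})

test_that("annotation readers reject labels outside the vocabulary", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "annot.tsv")
  writeLines(c("L1\tchemokine", "L2\tkinase activity"), tsv)
  expect_error(read_group_annotation(tsv), "kinase activity")
  gmt <- file.path(dir, "annot.gmt")
  writeLines(c("chemokine\tdesc\tL1\tR1", "cytokine\tdesc\tL2\tR2\tR3"), gmt)
  annot <- read_gmt_annotation(gmt)
  expect_equal(annot[["L1"]], "chemokine")
  expect_equal(annot[["R3"]], "cytokine")
})

test_that("intersection stats partition the merged catalog", {
  a <- quick_catalog(c("L1", "L2"), c("R1", "R2"), src = "A")
  b <- quick_catalog(c("L3", "L4", "L5"), c("R3", "R4", "R5"), src = "B")
  st <- intersection_stats(list(A = a, B = b))
  counts <- setNames(st$n_pairs, st$sources)
  expect_equal(counts[["A"]], 2)
  expect_equal(counts[["B"]], 3)
  expect_equal(counts[["A&B"]], 0)
  expect_equal(sum(st$n_pairs), attr(st, "merged_size"))
})

test_that("a pair present in all seven sources is counted as shared by all", {
  cats <- lapply(1:7, function(i) {
    quick_catalog(c("COMMON_L", sprintf("L%d", i)),
                  c("COMMON_R", sprintf("R%d", i)), src = paste0("S", i))
  })
  names(cats) <- paste0("S", 1:7)
  st <- intersection_stats(cats)
  expect_equal(attr(st, "shared_by_all"), 1)
  expect_equal(nrow(st), 127) # all non-empty subsets of 7 sources
})

test_that("intersection stats equal brute-force subset enumeration", {
  set.seed(99)
  k <- 7
  keysets <- lapply(1:k, function(i) sample.int(100, 50))
  cats <- lapply(keysets, function(ks) {
    quick_catalog(sprintf("L%03d", ks), sprintf("R%03d", ks),
                  src = "s")
  })
  names(cats) <- paste0("S", 1:k)
  st <- intersection_stats(cats)
  # oracle: enumerate all 127 subsets with plain set operations
  for (row in seq_len(nrow(st))) {
    members <- strsplit(st$sources[row], "&", fixed = TRUE)[[1]]
    idx <- match(members, names(cats))
    inside <- Reduce(intersect, keysets[idx])
    outside <- unique(unlist(keysets[-idx]))
    expected <- length(setdiff(inside, outside))
    expect_equal(st$n_pairs[row], expected)
  }
  expect_equal(sum(st$n_pairs), attr(st, "merged_size"))
})

test_that("intersection stats require at least two catalogs", {
  a <- quick_catalog("L1", "R1")
  expect_error(intersection_stats(list(a)), "at least 2")
})
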