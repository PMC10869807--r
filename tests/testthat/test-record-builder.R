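toy_country_db <- function() {
  paths <- make_fixture("toy-country")
  db <- load_occurrence_database(paths$occurrences, paths$basins)
  tree <- read_newick(paths$tree)
  list(db = db, tree = tree, D = cophenetic_distances(tree))
}

test_that("cleaning drops non-native-free units and off-tree species", {
  bas <- rbind(basin_row("b1", "X", "Palearctic"),
               basin_row("b2", "X", "Palearctic"),
               basin_row("b3", "Y", "Nearctic"))
  occ <- rbind(occ_row("A", "b1", "native"),
               occ_row("B", "b1", "nonnative"),
               occ_row("B", "b2", "native"),
               occ_row("C", "b3", "native"))   # country Y: natives only
  db <- occurrence_db(occ, bas)
  a <- classify_nonnatives(db, "country")
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cl <- clean_database(db, a, tree)
  expect_equal(cl$report$units_dropped, "Y")
  expect_equal(cl$report$n_basins_dropped, 1)
  expect_false("b3" %in% cl$db$basins$basin_id)
  expect_equal(cl$report$n_species_dropped, 0)

  # a species absent from the tree loses its records and is reported
  tree2 <- ape::read.tree(text = "(A:1,C:1);")
  cl2 <- clean_database(db, a, tree2)
  expect_equal(cl2$report$species_dropped, "B")
  expect_false("B" %in% cl2$db$records$species)

  # nothing to drop -> identity
  db_ok <- occurrence_db(occ[1:3, ], bas[1:2, ])
  cl3 <- clean_database(db_ok, classify_nonnatives(db_ok, "country"), tree)
  expect_equal(cl3$db$records, db_ok$records)
  expect_equal(cl3$report$n_units_dropped, 0)
})

test_that("record construction follows candidate-basin rules on the toy country", {
  tc <- toy_country_db()
  a <- classify_nonnatives(tc$db, "country")

  # exotic E present in b1 only: one row per basin of the country
  ex <- build_records(tc$db, a, tc$D, "exotic")
  expect_equal(nrow(ex), 3)
  expect_equal(ex$presence[match(c("b1", "b2", "b3"), ex$basin_id)],
               c(1L, 0L, 0L))

  # translocated T native in b1: origin basin excluded
  tr <- build_records(tc$db, a, tc$D, "translocated")
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$basin_id, c("b2", "b3"))
  expect_equal(tr$presence[match(c("b2", "b3"), tr$basin_id)], c(1L, 0L))

  # relatedness columns are populated and ordered
  expect_true(all(is.finite(ex$mpd)))
  expect_true(all(ex$mntd <= ex$mpd + 1e-12))
  expect_true(all(ex$basin_area > 0))
  expect_equal(ex$log_area, log(ex$basin_area))
})

test_that("a species invading two countries contributes records per unit", {
  bas <- rbind(basin_row("b1", "X", "Palearctic"),
               basin_row("b2", "X", "Palearctic"),
               basin_row("b3", "Y", "Palearctic"),
               basin_row("b4", "Y", "Palearctic"),
               basin_row("b5", "Y", "Palearctic"))
  occ <- rbind(occ_row("n1", c("b1", "b2", "b3", "b4", "b5"), "native"),
               occ_row("s", c("b1", "b3"), "nonnative"))
  db <- occurrence_db(occ, bas)
  a <- classify_nonnatives(db, "country")
  tree <- ape::read.tree(text = "((s:1,n1:1):1,x:2);")
  D <- cophenetic_distances(tree)
  rec <- build_records(db, a, D, "exotic")
  expect_equal(nrow(rec), 5)  # 2 basins in X + 3 in Y
  expect_equal(sum(rec$presence), 2)
  expect_setequal(unique(rec$country), c("X", "Y"))
})

test_that("record counts match the brute-force triple-loop oracle", {
  for (seed in c(4, 29)) {
    sim <- simulate_database(sim_config(n_species = 40, n_realms = 3,
                                        countries_per_realm = 1,
                                        basins_per_country = 4, seed = seed))
    a <- classify_nonnatives(sim$db, "country")
    cl <- clean_database(sim$db, a, sim$tree)
    D <- cophenetic_distances(sim$tree)
    a_cl <- classify_nonnatives(cl$db, "country")
    for (g in c("exotic", "translocated")) {
      n_oracle <- oracle_record_count(cl$db, "country", g)
      n_built <- tryCatch(nrow(build_records(cl$db, a_cl, D, g)),
                          error = function(e) 0L)
      expect_equal(n_built, n_oracle)
    }
  }
})

test_that("successes equal the group's non-native occurrences and never pair a species with its native basin", {
  sim <- simulate_database(sim_config(n_species = 60, seed = 13))
  a <- classify_nonnatives(sim$db, "country")
  cl <- clean_database(sim$db, a, sim$tree)
  D <- cophenetic_distances(sim$tree)
  a_cl <- classify_nonnatives(cl$db, "country")
  rec <- cl$db$records
  nat_key <- paste(rec$species[rec$status == "native"],
                   rec$basin_id[rec$status == "native"])
  for (g in c("exotic", "translocated")) {
    tab <- build_records(cl$db, a_cl, D, g)
    lab <- a_cl$labels
    expect_equal(sum(tab$presence), sum(lab$label == g))
    expect_false(any(paste(tab$species, tab$basin_id) %in% nat_key))
  }
})

test_that("the emitted table is invariant to input row order", {
  tc <- toy_country_db()
  a <- classify_nonnatives(tc$db, "country")
  rec1 <- build_records(tc$db, a, tc$D, "exotic")
  shuffled <- occurrence_db(tc$db$records[rev(seq_len(nrow(tc$db$records))), ],
                            tc$db$basins[rev(seq_len(nrow(tc$db$basins))), ])
  a2 <- classify_nonnatives(shuffled, "country")
  rec2 <- build_records(shuffled, a2, tc$D, "exotic")
  expect_equal(rec1, rec2, ignore_attr = "row.names")
})

test_that("basins whose natives vanish yield no records", {
  paths <- make_fixture("single-native-basin")
  db <- load_occurrence_database(paths$occurrences, paths$basins)
  tree <- read_newick(paths$tree)
  D <- cophenetic_distances(tree)
  a <- classify_nonnatives(db, "country")
  rec <- build_records(db, a, D, "exotic")
  # b2 has one native, so relatedness is defined; its diversity is not
  expect_true(all(c("b1", "b2") %in% rec$basin_id))
  expect_true(is.na(rec$native_mpd[rec$basin_id == "b2"][1]))
  expect_equal(rec$native_richness[rec$basin_id == "b2"][1], 1)
})

test_that("z-scoring uses the sample SD and is idempotent", {
  d <- data.frame(mpd = c(1, 2, 3))
  out <- standardize_records(d, "mpd")
  expect_equal(out$mpd_z, c(-1, 0, 1))
  out2 <- standardize_records(data.frame(mpd = out$mpd_z), "mpd")
  expect_equal(out2$mpd_z, out$mpd_z, tolerance = 1e-12)
  expect_error(standardize_records(data.frame(mpd = rep(2, 5)), "mpd"),
               "zero standard deviation")
  # emitted z columns have mean 0, sd 1 over the table
  sim <- simulate_database(sim_config(n_species = 50, seed = 19))
  a <- classify_nonnatives(sim$db, "country")
  cl <- clean_database(sim$db, a, sim$tree)
  D <- cophenetic_distances(sim$tree)
  tab <- standardize_records(build_records(cl$db,
                                           classify_nonnatives(cl$db, "country"),
                                           D, "exotic"))
  expect_equal(mean(tab$mpd_z), 0, tolerance = 1e-8)
  expect_equal(sd(tab$mpd_z), 1, tolerance = 1e-8)
  expect_equal(mean(tab$native_mntd_z, na.rm = TRUE), 0, tolerance = 1e-8)
})
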