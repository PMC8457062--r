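test_that("Fsp3 matches hand counts", {
  expect_equal(fsp3("C1CCCCC1"), 1.0)       # cyclohexane: all sp3
  expect_equal(fsp3("c1ccccc1"), 0.0)       # benzene: all aromatic
  expect_equal(fsp3("CCc1ccccc1"), 0.25)    # ethylbenzene: 2 of 8
  expect_equal(fsp3("C"), 1.0)              # methane
  expect_equal(fsp3("CC=O"), 0.5)           # acetaldehyde: 1 of 2
  expect_equal(fsp3("C#N"), 0.0)            # sp carbon
  expect_error(fsp3("O"), "no carbon")
  expect_error(fsp3("C((C"), "invalid SMILES")
})

test_that("Fsp3 stays within [0,1] across a large generated set", {
  corpus <- c(make_corpus("mixed", 1000, seed = 31),
              make_corpus("aromatics", 20, max_heavy_atoms = 14))
  vals <- fsp3(corpus)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(mean(fsp3(make_corpus("aromatics", 15, max_heavy_atoms = 14))),
            mean(fsp3(make_corpus("alkanes", 10))))
})

test_that("tanimoto follows the set-overlap formula", {
  f <- morgan_fingerprint(c("CCO", "CCO", "CCN"))
  expect_equal(tanimoto(f[1, ], f[2, ]), 1.0)
  a <- logical(8); a[1:3] <- TRUE
  b <- logical(8); b[2:4] <- TRUE
  expect_equal(tanimoto(a, b), 0.5)          # 2 shared of 4 total
  expect_equal(tanimoto(a, rep(TRUE, 8)), 3 / 8)
  expect_equal(tanimoto(a, !a), 0)           # disjoint
  expect_equal(tanimoto(logical(8), logical(8)), 0)  # declared 0/0 case
  expect_error(tanimoto(a, logical(4)), "length mismatch")
  expect_equal(tanimoto(f[1, ], f[3, ]), tanimoto(f[3, ], f[1, ]))
})

test_that("fingerprints honour the requested length and are deterministic", {
  f1 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O", radius = 2, n_bits = 1024)
  expect_identical(dim(f1), c(1L, 1024L))
  expect_gt(sum(f1), 0)
  f2 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O", radius = 2, n_bits = 1024)
  expect_identical(f1, f2)
  expect_error(morgan_fingerprint("C((C"), "invalid SMILES")
})

test_that("nearest-reference similarity returns the argmax reference", {
  designs <- c("CCO", "CCCC")
  refs <- c("CCO", "CCN")
  nr <- nearest_reference_similarity(designs, refs)
  expect_equal(nr$nearest_similarity[1], 1.0)
  expect_identical(nr$nearest_reference[1], "CCO")
  single <- nearest_reference_similarity(designs, "CCN")
  f <- morgan_fingerprint(c(designs, "CCN"))
  expect_equal(single$nearest_similarity[1], tanimoto(f[1, ], f[3, ]))
  expect_error(nearest_reference_similarity(designs, character(0)), "empty")
  self <- nearest_reference_similarity(designs, designs)
  expect_true(all(self$nearest_similarity == 1))
})

test_that("distance distributions match a brute-force double loop", {
  mols <- c("CCO", "CCN", "CCC", "CCCO")
  f <- morgan_fingerprint(mols)
  brute <- c()
  for (i in 1:3) for (j in (i + 1):4)
    brute <- c(brute, 1 - tanimoto(f[i, ], f[j, ]))
  dd <- distance_distribution(mols)
  expect_length(dd$distances, 6)
  expect_equal(sort(dd$distances), sort(brute))
  expect_equal(unname(dd$summary["median"]), stats::median(brute))
  expect_equal(unname(dd$summary["mean"]), mean(brute))
  expect_equal(unname(dd$summary[c("q25", "q75")]),
               unname(stats::quantile(brute, c(.25, .75))))

  # between-set mode: all cross pairs
  dd2 <- distance_distribution(mols[1:2], mols[3:4])
  cross <- c(1 - tanimoto(f[1, ], f[3, ]), 1 - tanimoto(f[2, ], f[3, ]),
             1 - tanimoto(f[1, ], f[4, ]), 1 - tanimoto(f[2, ], f[4, ]))
  expect_equal(sort(dd2$distances), sort(cross))
})

test_that("distance distribution degenerate cases", {
  expect_error(distance_distribution("CCO"), "at least 2")
  two <- distance_distribution(c("CCO", "CCN"))
  expect_length(two$distances, 1)
  expect_true(all(two$summary[c("q25", "median", "q75", "mean")] ==
                    two$distances))
  same <- distance_distribution(c("CCO", "OCC", "CCO"))
  expect_true(all(same$distances == 0))
  expect_true(all(same$summary == 0))
})

test_that("duplicating a set leaves within-set quantiles unchanged in spread", {
  mols <- c("CCO", "CCN", "CCCC", "c1ccccc1")
  d1 <- distance_distribution(mols)
  d2 <- distance_distribution(rep(mols, 2))
  # duplicated records add zero self-distances and repeat each pair; the
  # extreme quantiles of the nonzero spread are preserved
  expect_equal(max(d2$distances), max(d1$distances))
  expect_true(all(unique(round(d2$distances, 12)) %in%
                    c(0, round(d1$distances, 12))))
})
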