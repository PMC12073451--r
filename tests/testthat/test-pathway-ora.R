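test_that("hypergeometric upper tail equals exhaustive enumeration", {
  for (N in c(5, 8, 12)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(ora_pvalue(k, K, n, N), bf_hyper_upper(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("p-value boundary cases and monotonicity hold", {
  expect_identical(ora_pvalue(0, 10, 5, 100), 1)
  expect_identical(ora_pvalue(5, 5, 5, 5), 1)  # forced complete overlap
  p <- vapply(0:5, ora_pvalue, numeric(1), pathway_size = 8,
              query_size = 5, universe_size = 30)
  expect_true(all(diff(p) <= 0))
  expect_error(ora_pvalue(3, 2, 5, 10), "inconsistent")
  expect_error(ora_pvalue(1, 20, 5, 10), "inconsistent")
})

test_that("impact matches brute-force betweenness on the path graph", {
  path3 <- list(members = c("a", "b", "c"),
                edges = list(c("a", "b"), c("b", "c")))
  expect_identical(pathway_impact(path3, "b"), 1)
  expect_identical(pathway_impact(path3, "a"), 0)
  expect_identical(pathway_impact(path3, character(0)), 0)
  expect_identical(pathway_impact(path3, c("a", "b", "c")), 1)
  expect_error(pathway_impact(path3, "z"), "not members")
})

test_that("impact agrees with geodesic-enumeration oracle on random graphs", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    members <- letters[1:n]
    # random connected-ish graph: spanning chain + extras
    edges <- lapply(seq_len(n - 1), function(i) {
      c(members[sample.int(i, 1)], members[i + 1])
    })
    for (e in seq_len(sample(0:3, 1))) {
      edges[[length(edges) + 1]] <- sample(members, 2)
    }
    bc <- bf_betweenness(members, edges)
    rbc <- if (sum(bc) == 0) rep(1 / n, n) else bc / sum(bc)
    names(rbc) <- members
    hits <- sample(members, sample.int(n, 1))
    expect_equal(pathway_impact(list(members = members, edges = edges),
                                hits),
                 sum(rbc[hits]), tolerance = 1e-12)
  }
  # impact is additive over disjoint hit sets
  pw <- list(members = letters[1:6],
             edges = list(c("a","b"), c("b","c"), c("c","d"), c("d","e"),
                          c("e","f")))
  expect_equal(pathway_impact(pw, c("b", "c")),
               pathway_impact(pw, "b") + pathway_impact(pw, "c"),
               tolerance = 1e-12)
})

test_that("the packaged demo library loads, validates, and round-trips", {
  lib <- read_pathway_library()
  expect_s3_class(lib, "pathway_library")
  expect_identical(length(lib$pathways), 10L)
  sizes <- vapply(lib$pathways, function(p) length(p$members), integer(1))
  expect_identical(sizes[1], 29L)  # arginine/proline-style pathway
  tmp <- tempfile(fileext = ".json")
  write_pathway_library(lib, tmp)
  lib2 <- read_pathway_library(tmp)
  expect_identical(lib2$universe, lib$universe)
  expect_identical(lib2$pathways[[3]]$members, lib$pathways[[3]]$members)
})

test_that("query analysis ranks an exactly-covered pathway first", {
  lib <- read_pathway_library()
  res <- analyze_pathways(lib$pathways[[5]]$members, lib)
  expect_identical(res$pathway[1], lib$pathways[[5]]$name)
  expect_identical(res$hits[1], res$total[1])
  # disjoint query: no results; unmapped compounds reported
  res0 <- analyze_pathways(c("nothing_1", "nothing_2"), lib)
  expect_identical(nrow(res0), 0L)
  expect_identical(attr(res0, "unmapped"), c("nothing_1", "nothing_2"))
  bad <- list(universe = character(0), pathways = list())
  expect_error(analyze_pathways("x", bad), "empty")
})

test_that("planted enrichment is detected in random libraries", {
  top2 <- 0L
  for (s in 1:100) {
    set.seed(s)
    lib <- simulate_pathway_library(20, 200)
    planted <- lib$pathways[1:2]
    query <- unique(c(
      unlist(lapply(planted, function(p) {
        sample(p$members, ceiling(0.6 * length(p$members)))
      })),
      sample(lib$universe, 5)
    ))
    res <- analyze_pathways(query, lib)
    nm <- vapply(planted, `[[`, character(1), "name")
    if (all(nm %in% res$pathway[1:2])) top2 <- top2 + 1L
  }
  expect_gte(top2, 90L)
})
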