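test_that("GMT files parse into named member lists", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst pathway\tg1\tg2\tg3",
               "setB\tsecond\tg2\tg4"), gmt)
  sets <- read_gmt(gmt)
  expect_named(sets, c("setA", "setB"))
  expect_setequal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(attr(sets, "descriptions")[["setB"]], "second")
})

make_instance <- function(a, b, c_set, d) {
  background <- sprintf("g%03d", seq_len(d))
  set_members <- background[seq_len(c_set)]
  markers <- c(background[seq_len(a)],                       # in the set
               background[c_set + seq_len(b - a)])           # outside it
  list(markers = markers, sets = list(S = set_members), bg = background)
}

test_that("enrichment ratio follows [a/b]/[c/d]", {
  i1 <- make_instance(5, 10, 500, 1000)
  r1 <- enrich_emdr(i1$markers, i1$sets, i1$bg)
  expect_equal(r1$ratio, 1)
  expect_equal(c(r1$a, r1$b, r1$c, r1$d), c(5, 10, 500, 1000))

  i2 <- make_instance(5, 10, 50, 1000)
  expect_equal(enrich_emdr(i2$markers, i2$sets, i2$bg)$ratio, 10)

  # invariance under proportional scaling of (a, b) and (c, d)
  i3 <- make_instance(10, 20, 100, 2000)
  expect_equal(enrich_emdr(i3$markers, i3$sets, i3$bg)$ratio, 10)

  expect_error(enrich_emdr(c("zz"), i1$sets, i1$bg), "subset")
  expect_error(enrich_emdr("g001", i1$sets, character(0)), "background")
  expect_equal(nrow(enrich_emdr(character(0), i1$sets, i1$bg)), 0L)
})

test_that("hypergeometric p equals exhaustive enumeration end to end", {
  # through the user-facing operation on a lattice of small instances
  for (d in c(8L, 15L, 20L, 25L)) {
    for (c_set in c(3L, d %/% 2, d - 2L)) {
      for (b in c(2L, d %/% 3, d %/% 2)) {
        for (a in 0:min(b, c_set)) {
          if (b - a > d - c_set) next
          inst <- make_instance(a, b, c_set, d)
          got <- enrich_emdr(inst$markers, inst$sets, inst$bg)
          expect_equal(got$p, oracle_hyper_upper(a, c_set, d, b),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("delta enrichment cancels, negates on side swap, and finds planted sets", {
  e_s <- data.frame(set_id = c("A", "B"), ratio = c(2, 1))
  e_r <- data.frame(set_id = c("A", "C"), ratio = c(2, 3))
  d1 <- delta_enrichment(e_s, e_r)
  expect_equal(d1[["A"]], 0)           # equal ratios cancel
  expect_equal(d1[["B"]], 1)           # missing side contributes 0
  expect_equal(d1[["C"]], -3)
  d2 <- delta_enrichment(e_r, e_s)
  expect_equal(unname(d2[names(d1)]), -unname(d1), ignore_attr = TRUE)

  # a drug whose sensitivity markers are drawn from one set maximizes its delta
  bg <- sprintf("g%03d", 1:60)
  sets <- list(hit = bg[1:12], other1 = bg[13:30], other2 = bg[31:48])
  cat1 <- structure(list(drugX = list(
    sensitivity = bg[1:8], resistance = bg[41:48],
    support = NULL, n_retained = 10L, status = "ok")),
    class = "emdr_catalog")
  enr <- enrich_catalog(cat1, sets, bg)
  expect_equal(names(which.max(enr$delta["drugX", ])), "hit")
})

test_that("similarity scores scale to median 0 / sd 1 and match the covariance oracle", {
  set.seed(31)
  delta <- matrix(rnorm(5 * 8), 5, 8,
                  dimnames = list(paste0("d", 1:5), paste0("s", 1:8)))
  delta[2, ] <- delta[1, ]             # identical profiles
  sim <- similarity_scores(delta)
  expect_equal(sim$r["d1", "d2"], 1)
  expect_equal(max(sim$score[upper.tri(sim$score)]), sim$score["d1", "d2"])
  off <- sim$score[upper.tri(sim$score)]
  expect_equal(median(off), 0, tolerance = 1e-9)
  expect_equal(sd(off), 1, tolerance = 1e-9)
  # symmetry and consistent permutation
  expect_equal(sim$r, t(sim$r))
  perm <- c(3, 1, 5, 2, 4)
  sim2 <- similarity_scores(delta[perm, ])
  expect_equal(sim2$r[rownames(sim$r), colnames(sim$r)], sim$r)

  # raw r matches a direct covariance-formula computation
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(sim$r[i, j], pearson(delta[i, ], delta[j, ]),
                 tolerance = 1e-12)

  # constant profile yields missing pairs
  delta2 <- delta; delta2[3, ] <- 2
  sim3 <- similarity_scores(delta2)
  expect_true(all(is.na(sim3$r["d3", -3])))
})

test_that("drug clusters sharing response structure are more similar within than between", {
  pipe <- ref_pipeline()
  inp <- ref_inputs()
  # gene sets built from the generator's marker blocks per cluster
  truth <- inp$truth
  bg <- rownames(inp$omics$values)
  # one sensitivity-block and one resistance-block set per drug cluster
  by_cluster <- split(names(truth$cluster_of), truth$cluster_of)
  sets <- c(
    lapply(by_cluster, function(ds)
      unique(unlist(lapply(truth$drugs[ds], `[[`, "sensitivity")))),
    lapply(by_cluster, function(ds)
      unique(unlist(lapply(truth$drugs[ds], `[[`, "resistance")))))
  names(sets) <- c(paste0("cluster_up_", names(by_cluster)),
                   paste0("cluster_dn_", names(by_cluster)))
  enr <- enrich_catalog(pipe$catalog, sets, bg)
  sim <- similarity_scores(enr$delta)
  cl <- truth$cluster_of[rownames(sim$r)]
  same <- outer(cl, cl, "==") & upper.tri(sim$r)
  diff_cl <- outer(cl, cl, "!=") & upper.tri(sim$r)
  expect_gt(mean(sim$r[same], na.rm = TRUE),
            mean(sim$r[diff_cl], na.rm = TRUE))
})
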