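test_that("direction-aware ranking follows the metric definitions", {
  hi <- component_score("c1", "d1", "abundance", c(A = 5, B = 2, C = 9))
  rv <- rank_with_direction(hi)
  expect_equal(setNames(rv$rank, rv$symbol), c(A = 2, B = 3, C = 1))
  expect_identical(unique(rv$x), 3L)

  tie <- component_score("c2", "d1", "abundance", c(A = 4, B = 4, C = 1))
  rv <- rank_with_direction(tie)
  expect_equal(setNames(rv$rank, rv$symbol), c(A = 1.5, B = 1.5, C = 3))

  lo <- component_score("c3", "d1", "p_diff", c(A = 0.01, B = 0.5))
  rv <- rank_with_direction(lo)
  expect_equal(setNames(rv$rank, rv$symbol), c(A = 1, B = 2))

  empty <- component_score("c4", "d1", "p_diff", c(A = NA_real_))
  expect_error(rank_with_direction(empty), "nothing to rank")
})

test_that("rank vectors sum to x(x+1)/2 and put the best value first", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    metric <- sample(names(oncorank:::METRIC_DIRECTIONS), 1)
    vals <- round(rlnorm(n, 1, 1.5), sample(0:3, 1))  # ties likely
    names(vals) <- paste0("P", seq_len(n))
    rv <- rank_with_direction(component_score("c", "d", metric, vals))
    expect_equal(sum(rv$rank), n * (n + 1) / 2)
    expect_true(all(rv$rank >= 1 & rv$rank <= n))
    best <- rv$symbol[rv$rank == min(rv$rank)]
    target <- if (oncorank:::METRIC_DIRECTIONS[[metric]] == "higher_is_better") {
      names(vals)[vals == max(vals)]
    } else {
      names(vals)[vals == min(vals)]
    }
    expect_setequal(best, target)
  }
})

test_that("candidate intersection is a sorted Venn overlap", {
  expect_identical(intersect_candidates(list(c("A", "B"), c("B", "C"))), "B")
  expect_identical(intersect_candidates(list(c("B", "A"))), c("A", "B"))
  expect_identical(intersect_candidates(list(c("A"), c("B"))), character())
  expect_error(intersect_candidates(list()), "at least one")
})

test_that("Rscore reproduces the weighted mean-rank arithmetic", {
  rv <- function(id, ranks) {
    tibble::tibble(component_id = id, symbol = names(ranks),
                   rank = unname(ranks), x = length(ranks))
  }
  # single component, weight 1: Rscore is the rank itself
  one <- rv("a", c(P1 = 2, P2 = 1, P3 = 3))
  rs <- compute_rscore(one)
  expect_equal(setNames(rs$rscore, rs$symbol)[names(c(P1 = 2, P2 = 1, P3 = 3))],
               c(P1 = 2, P2 = 1, P3 = 3))

  # ranks (2, 4, 6) with unit weights: (2 + 4 + 6)/3 = 4
  three <- dplyr::bind_rows(rv("a", c(P = 2, Q = 1)),
                            rv("b", c(P = 4, Q = 1)),
                            rv("c", c(P = 6, Q = 1)))
  rs <- compute_rscore(three)
  expect_equal(rs$rscore[rs$symbol == "P"], 4)

  # ranks (2, 5, 1), weights (1, 0.5, 2): (2 + 2.5 + 2)/3 = 13/6
  cfg <- rscore_config(components = tibble::tibble(
    component_id = c("a", "b", "c"), weight = c(1, 0.5, 2)
  ))
  weighted <- dplyr::bind_rows(rv("a", c(P = 2, Q = 1)),
                               rv("b", c(P = 5, Q = 1)),
                               rv("c", c(P = 1, Q = 2)))
  rs <- compute_rscore(weighted, cfg)
  expect_equal(rs$rscore[rs$symbol == "P"], 13 / 6)

  # percentile scale divides each rank by its component size first
  cfg_pct <- rscore_config(rank_scale = "percentile")
  rs_pct <- compute_rscore(one, cfg_pct)
  expect_equal(setNames(rs_pct$rscore, rs_pct$symbol)[c("P1", "P2", "P3")],
               c(P1 = 2, P2 = 1, P3 = 3) / 3)
})

test_that("missing-data policies score the intended protein sets", {
  rv_a <- tibble::tibble(component_id = "a", symbol = c("P", "Q", "R"),
                         rank = c(1, 2, 3), x = 3L)
  rv_b <- tibble::tibble(component_id = "b", symbol = c("P", "Q"),
                         rank = c(2, 1), x = 2L)
  both <- dplyr::bind_rows(rv_a, rv_b)

  inter <- compute_rscore(both, rscore_config(missing_policy = "intersection"))
  expect_setequal(inter$symbol, c("P", "Q"))
  expect_equal(inter$rscore[inter$symbol == "P"], (1 + 2) / 2)

  adj <- compute_rscore(both, rscore_config(missing_policy = "adjusted_n"))
  expect_setequal(adj$symbol, c("P", "Q", "R"))
  expect_equal(adj$rscore[adj$symbol == "R"], 3)   # n = 1 for R
  expect_equal(adj$n_used[adj$symbol == "R"], 1L)

  # zero-weight components are dropped and do not count toward n
  cfg0 <- rscore_config(components = tibble::tibble(
    component_id = c("a", "b"), weight = c(1, 0)
  ))
  only_a <- compute_rscore(both, cfg0)
  expect_setequal(only_a$symbol, c("P", "Q", "R"))
  expect_equal(only_a$rscore[only_a$symbol == "R"], 3)
})

test_that("Rscore is monotone and Borda-equivalent under unit weights", {
  set.seed(321)
  for (i in 1:30) {
    n_prot <- sample(4:25, 1)
    n_comp <- sample(2:6, 1)
    symbols <- paste0("P", seq_len(n_prot))
    ranks <- dplyr::bind_rows(lapply(seq_len(n_comp), function(k) {
      tibble::tibble(component_id = paste0("c", k), symbol = symbols,
                     rank = sample(n_prot), x = n_prot)
    }))
    rs <- compute_rscore(ranks)
    orc <- oracle_mean_rank(ranks)
    expect_identical(rs$symbol, orc$symbol)
    expect_equal(rs$rscore, orc$rank)

    # improving one component's rank strictly decreases the Rscore
    pick <- which(ranks$component_id == "c1" & ranks$rank > 1)[1]
    improved <- ranks
    improved$rank[pick] <- improved$rank[pick] - 1
    rs2 <- compute_rscore(improved, rscore_config())
    sym <- ranks$symbol[pick]
    expect_lt(rs2$rscore[rs2$symbol == sym], rs$rscore[rs$symbol == sym])

    # relabeling proteins and reordering components is irrelevant
    relab <- setNames(paste0("Q", seq_len(n_prot)), symbols)
    shuffled <- ranks[sample(nrow(ranks)), ]
    shuffled$symbol <- unname(relab[shuffled$symbol])
    rs3 <- compute_rscore(shuffled)
    expect_equal(setNames(rs3$rscore, rs3$symbol)[unname(relab[rs$symbol])],
                 setNames(rs$rscore, unname(relab[rs$symbol])))
  }
})

test_that("final ranking sorts ascending with lexicographic tie-break", {
  rs <- tibble::tibble(symbol = c("A", "B"), rscore = c(4, 2.1),
                       n_used = 2L)
  rep <- final_ranking(rs)
  expect_identical(rep$symbol, c("B", "A"))
  expect_identical(rep$final_rank, 1:2)

  tied <- tibble::tibble(symbol = c("B", "A"), rscore = c(3, 3), n_used = 1L)
  rep <- final_ranking(tied)
  expect_identical(rep$symbol, c("A", "B"))

  single <- final_ranking(tibble::tibble(symbol = "Z", rscore = 1,
                                         n_used = 1L))
  expect_identical(single$final_rank, 1L)
  expect_error(final_ranking(tied[0, ]), "empty")
})
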