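test_that("partitioning by 5' base splits U-starting from the rest", {
  qs <- query_set(c("q1", "q2", "q3"), c("TAAA", "CAAA", "TCCC"))
  p <- partition_sequences(qs, "starts_with_U")
  expect_equal(p$count_A, 2)
  expect_equal(p$count_B, 1)

  plasma <- load_plasma_pirnas()
  pp <- partition_sequences(plasma, "starts_with_U")
  expect_equal(pp$count_A, 9)
  expect_equal(pp$count_B, 16)
  # weights are the summed RPM of each category
  expect_equal(pp$weight_A + pp$weight_B, sum(plasma$rpm))

  expect_error(partition_sequences(query_set(character(0), character(0))),
               "empty")
})

test_that("partitioning by ncRNA identity needs complete annotations", {
  ann <- plasma_annotations()
  qs <- load_plasma_pirnas()
  p <- partition_sequences(qs, "matches_ncRNA", ann)
  expect_equal(p$count_B, 17)  # the ncRNA-fragment rows
  expect_equal(p$count_A, 8)
  expect_error(partition_sequences(qs, "matches_ncRNA", ann[-1, ]),
               "missing annotations")
})

test_that("the enrichment score follows the ratio-of-ratios closed forms", {
  # proportional query: unity
  expect_equal(enrichment_score(category_partition(90, 10),
                                category_partition(45, 5))$es_by_count, 1.0)
  # direct arithmetic
  expect_equal(enrichment_score(category_partition(90, 10),
                                category_partition(5, 5))$es_by_count, 9.0)
  # degenerate query (all in B) on database-scale reference counts
  deg <- enrichment_score(category_partition(171159, 392),
                          category_partition(0, 25))
  expect_equal(deg$es_by_count, Inf)
  expect_true("query_A_zero" %in% deg$flags)
  # empty-B query scores zero
  expect_equal(enrichment_score(category_partition(90, 10),
                                category_partition(25, 0))$es_by_count, 0)
  # reference with an empty category is an error
  expect_error(enrichment_score(category_partition(0, 100),
                                category_partition(5, 5)), "reference")
  # pseudocount renders the degenerate case finite
  ps <- enrichment_score(category_partition(171159, 392),
                         category_partition(0, 25), pseudocount = TRUE)
  expect_true(is.finite(ps$es_by_count))
})

test_that("ES invariances hold over random partitions", {
  set.seed(23)
  for (i in 1:25) {
    rA <- sample(50:500, 1); rB <- sample(50:500, 1)
    qA <- sample(1:50, 1); qB <- sample(1:50, 1)
    ref <- category_partition(rA, rB)
    qry <- category_partition(qA, qB)
    es <- enrichment_score(ref, qry)$es_by_count
    # self-comparison is exactly 1
    expect_equal(enrichment_score(ref, ref)$es_by_count, 1.0)
    # scaling the query counts leaves ES unchanged
    k <- sample(2:7, 1)
    expect_equal(enrichment_score(ref, category_partition(k * qA, k * qB))$es_by_count,
                 es)
    # swapping A and B in both partitions inverts ES
    expect_equal(enrichment_score(category_partition(rB, rA),
                                  category_partition(qB, qA))$es_by_count,
                 1 / es)
  }
})

test_that("equal weights make the weighted ES equal the count ES", {
  ref <- category_partition(120, 30, weight_A = 120 * 2.5, weight_B = 30 * 2.5)
  qry <- category_partition(10, 20, weight_A = 10 * 2.5, weight_B = 20 * 2.5)
  res <- enrichment_score(ref, qry, use_weights = TRUE)
  expect_equal(res$es_by_weight, res$es_by_count)
  expect_length(res$flags, 0L)
  expect_error(enrichment_score(category_partition(1, 1),
                                category_partition(1, 1), use_weights = TRUE),
               "weights")
})

test_that("enrichment results serialize to JSON and back", {
  res <- enrichment_score(category_partition(90, 10), category_partition(5, 5))
  js <- jsonlite::fromJSON(enrichment_json(res))
  expect_equal(js$es_by_count, 9)
  expect_equal(js$ref_partition$count_A, 90)
})

test_that("the overlap p-value is the upper-tail hypergeometric", {
  expect_equal(overlap_pvalue(100, 10, 10, 0), 1.0)
  expect_equal(overlap_pvalue(10, 5, 5, 5), 1 / 252)
  # exhaustive-enumeration oracle on small universes
  set.seed(12)
  for (i in 1:6) {
    N <- sample(10:30, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:min(8, N - 1), 1)
    q <- sample(0:min(K, n), 1)
    expect_equal(overlap_pvalue(N, K, n, q), enumerate_overlap_tail(N, K, n, q),
                 tolerance = 1e-12)
  }
  expect_error(overlap_pvalue(100, 2, 20, 3), "exceeds")
  expect_error(overlap_pvalue(10, 20, 5, 2), "universe")
})
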