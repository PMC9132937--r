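# Core regional signatures, K-means profiles, overlap, PCA, UPGMA, joint
# integration matrix.

region_design <- function(regions, n_per_region) {
  ids <- as.vector(vapply(regions, function(r)
    sprintf("%s_%d", r, seq_len(n_per_region)), character(n_per_region)))
  sample_design(ids, genotype = "labeled",
                region = rep(regions, each = n_per_region), mouse_id = ids)
}

test_that("a zero-noise planted regional protein lands in exactly its
           region; constants land nowhere", {
  regions <- c("A", "B", "C", "D")
  design <- region_design(regions, 3)
  v <- matrix(20, 3, 12,
              dimnames = list(c("flat", "inA", "jitter"),
                              design$sample_id))
  v["inA", design$region == "A"] <- 23       # 8-fold, zero noise
  # give the rest-group some variance so the t-test is well-defined
  v["jitter", ] <- 20 + seq(0, 1.1, length.out = 12)
  v["inA", design$region != "A"] <- 20 + rep(c(-0.01, 0, 0.01), 3)
  mat <- intensity_matrix(v, scale = "log2")
  sig <- core_signatures(mat, design, fc_core = 4)
  expect_equal(sig$signatures$A$protein_group_id, "inA")
  expect_equal(nrow(sig$signatures$B), 0)
  expect_false("flat" %in% sig$assignment$protein_group_id)
})

test_that("multi-region qualifiers go to the max fold-change region and are
           flagged", {
  regions <- c("A", "B", "C", "D")
  design <- region_design(regions, 6)
  jit <- seq(-0.05, 0.05, length.out = 6)
  v <- matrix(20, 2, 24, dimnames = list(c("both", "ref"),
                                         design$sample_id))
  v["both", design$region == "A"] <- 28 + jit     # 256-fold over baseline
  v["both", design$region == "B"] <- 27.5 + jit
  v["both", design$region == "C"] <- 20 + jit
  v["both", design$region == "D"] <- 20 + jit
  v["ref", ] <- 20 + seq(0, 1, length.out = 24)
  mat <- intensity_matrix(v, scale = "log2")
  sig <- core_signatures(mat, design, fc_core = 4)
  asn <- sig$assignment[sig$assignment$protein_group_id == "both", ]
  expect_equal(asn$region, "A")
  expect_true(asn$multi_region)
  expect_equal(nrow(sig$signatures$B), 0)
})

test_that("region grouping merges regions, small regions error", {
  design <- region_design(c("CTX", "HIP", "CB"), 2)
  v <- matrix(rnorm(24, 20), 4, 6,
              dimnames = list(sprintf("p%d", 1:4), design$sample_id))
  mat <- intensity_matrix(v, scale = "log2")
  groups <- list(CTX_HIP = c("CTX", "HIP"), CB = "CB")
  sig <- core_signatures(mat, design, region_groups = groups)
  expect_setequal(names(sig$signatures), c("CTX_HIP", "CB"))

  d1 <- region_design(c("A", "B"), 2)
  d1$region[1] <- "C"   # region C with a single sample
  m1 <- intensity_matrix(matrix(rnorm(8, 20), 2, 4,
                                dimnames = list(c("x", "y"),
                                                d1$sample_id)),
                         scale = "log2")
  expect_error(core_signatures(m1, d1), "fewer than 2")
})

test_that("K-means recovers two well-separated planted profile groups", {
  set.seed(17)
  up <- c(2, 2, -2, -2, 0, 0)
  down <- -up
  v <- rbind(matrix(rep(up, each = 15), 15) + rnorm(90, 0, 0.05),
             matrix(rep(down, each = 15), 15) + rnorm(90, 0, 0.05))
  dimnames(v) <- list(sprintf("p%d", 1:30), sprintf("s%d", 1:6))
  km <- kmeans_profiles(v, k = 2, seed = 3)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(km$assignment == truth),
               mean(km$assignment == 3 - truth))
  expect_equal(agree, 1)
  # determinism for a fixed seed
  km2 <- kmeans_profiles(v, k = 2, seed = 3)
  expect_identical(km$assignment, km2$assignment)
})

test_that("K-means flags constant rows and collapses duplicate profiles", {
  v <- matrix(rep(c(1, 2, 3), each = 4), 4, 3, byrow = FALSE,
              dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:3)))
  v[4, ] <- 5  # constant row
  expect_warning(expect_warning(km <- kmeans_profiles(v, k = 2, seed = 1),
                                "constant"), "distinct")
  expect_equal(km$k_effective, 1)
  expect_equal(km$dropped, "p4")
  expect_error(kmeans_profiles(v, k = 10, seed = 1), "exceeds")
})

test_that("overlap percentages reproduce hand counts and respect case", {
  mk_sig <- function(lists) {
    sigs <- lapply(lists, function(ids)
      data.frame(protein_group_id = ids, region = NA, log2_fc = 3,
                 p_value = 0.01, multi_region = FALSE))
    structure(list(signatures = sigs,
                   assignment = do.call(rbind, sigs),
                   region_groups = as.list(names(lists)), fc_core = 4,
                   p_threshold = 0.05),
              class = "regional_signature_set")
  }
  e_ids <- sprintf("gene%04d", 1:549)
  b_ids <- c(toupper(e_ids[1:419]), sprintf("other%d", 1:100))
  ov <- overlap_with_background(mk_sig(list(CTX_HIP = e_ids)),
                                mk_sig(list(CTX_HIP = b_ids)))
  expect_equal(ov$n_intersection, 419)
  expect_equal(round(ov$percent_overlap, 1), 76.3)

  ident <- overlap_with_background(mk_sig(list(R = e_ids[1:10])),
                                   mk_sig(list(R = e_ids[1:10])))
  expect_equal(ident$percent_overlap, 100)
  disj <- overlap_with_background(mk_sig(list(R = e_ids[1:10])),
                                  mk_sig(list(R = e_ids[21:30])))
  expect_equal(disj$percent_overlap, 0)
  expect_length(disj$exclusive_to_enriched[[1]], 10)
  expect_error(overlap_with_background(mk_sig(list(R = e_ids[1:3])),
                                       mk_sig(list(S = e_ids[1:3]))),
               "region sets differ")
})

test_that("PCA fractions: collinear points give PC1 = 1; a diag(2,1)
           covariance gives 2/3 and 1/3", {
  v <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3,
              dimnames = list(c("x", "y"), c("s1", "s2", "s3")))
  p <- run_pca(v)
  expect_equal(p$variance_fractions_all[1], 1)

  # 4 samples whose sample covariance is exactly diag(2, 1)
  a <- sqrt(3); b <- sqrt(1.5)
  v2 <- rbind(x = c(a, -a, 0, 0), y = c(0, 0, b, -b))
  colnames(v2) <- sprintf("s%d", 1:4)
  p2 <- run_pca(v2)
  expect_equal(p2$variance_fractions_all, c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(sum(p2$variance_fractions_all), 1, tolerance = 1e-9)
  # non-increasing fractions and fixed sign convention
  expect_true(all(diff(p2$variance_fractions_all) <= 0))
  expect_true(all(apply(p2$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_error(run_pca(v[, 1, drop = FALSE]), "at least 2")
})

test_that("correlation distances hit their extremes and UPGMA matches the
           brute-force oracle", {
  # perfectly correlated and anticorrelated pairs
  v <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  colnames(v) <- sprintf("s%d", 1:4)
  h <- hca(v, axis = "rows")
  d <- as.matrix(h$dist)
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_equal(sort(h$tree$merge[1, ]), c(-2, -1))  # a,b merged first

  set.seed(41)
  for (n_items in 3:6) {
    v2 <- matrix(rnorm(n_items * 8), n_items,
                 dimnames = list(sprintf("i%d", seq_len(n_items)),
                                 sprintf("f%d", 1:8)))
    h2 <- hca(v2, axis = "rows")
    D <- as.matrix(h2$dist)
    oracle <- upgma_oracle(D)
    expect_equal(as.matrix(cophenetic(h2$tree))[rownames(D), rownames(D)],
                 oracle$cophenetic, tolerance = 1e-9)
    expect_equal(sort(h2$tree$height), oracle$heights, tolerance = 1e-9)
    # merge heights are non-decreasing (UPGMA is monotone)
    expect_true(all(diff(h2$tree$height) >= -1e-12))
  }

  vc <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_error(hca(vc, axis = "rows"), "constant")
})

test_that("annotation-list intersection counts and breakdown", {
  expect_equal(nrow(annotate_with_list(sprintf("g%d", 1:10),
                                       c("g2", "g5", "zz", "yy"))), 2)
  expect_equal(nrow(annotate_with_list(letters[1:3], LETTERS[1:3])), 3)
  expect_equal(nrow(annotate_with_list(letters[1:3], c("x", "y"))), 0)
  expect_error(annotate_with_list(letters, character()), "empty")
  df <- data.frame(protein_group_id = c("Gfap", "Syn1", "Alb"),
                   region = c("CTX", "CTX", "CB"))
  out <- annotate_with_list(df, c("GFAP", "ALB"), list_name = "druggable")
  expect_equal(out$region, c("CTX", "CB"))
  expect_equal(unique(out$list_name), "druggable")
})

test_that("joint signature matrix z-scores every feature across regions", {
  regions <- c("CTX", "HIP", "ST", "CB")
  ms <- matrix(rnorm(12, 20), 3, 4,
               dimnames = list(sprintf("p%d", 1:3), regions))
  lx <- matrix(rnorm(8, 100, 20), 2, 4,
               dimnames = list(c("IL6", "TNF"), rev(regions)))
  jm <- joint_signature_matrix(ms, lx)
  expect_equal(dim(jm$matrix), c(5, 4))
  expect_equal(unname(rowMeans(jm$matrix)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(jm$matrix, 1, sd)), rep(1, 5),
               tolerance = 1e-9)

  # constant feature dropped with warning
  ms2 <- ms
  ms2[1, ] <- 7
  expect_warning(jm2 <- joint_signature_matrix(ms2, lx), "constant")
  expect_equal(jm2$dropped, "p1")

  expect_error(joint_signature_matrix(ms[, 1, drop = FALSE],
                                      lx[, "CTX", drop = FALSE]),
               "at least 2")
  colnames(lx) <- c("CTX", "HIP", "ST", "XX")
  expect_error(joint_signature_matrix(ms, lx), "region labels differ")

  # pluggable embedder: only the output shape is contractual
  emb <- joint_signature_matrix(ms, matrix(rnorm(8), 2, 4,
                                           dimnames = list(c("IL6", "TNF"),
                                                           regions)),
                                embedder = function(x, seed)
                                  run_pca(t(x))$scores[, 1:2])
  expect_equal(dim(emb$embedding), c(5, 2))
})
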