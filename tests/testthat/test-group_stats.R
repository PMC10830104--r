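test_that("ANOVA F matches the textbook sums-of-squares oracle", {
  groups <- list(c(4.1, 5.2, 3.9), c(6.0, 5.5, 6.3, 5.8),
                 c(2.2, 2.9, 3.1, 2.4, 2.7))
  res <- one_way_anova(groups)
  # independent oracle from the definition
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (sapply(groups, mean) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  g <- length(groups); n <- length(y)
  F_oracle <- (ssb / (g - 1)) / (ssw / (n - g))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 9L)
  expect_equal(res$p, stats::pf(F_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("groups with identical contents give F = 0", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g)$F, 0, tolerance = 1e-10)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  x <- rnorm(6); y <- rnorm(8, 1)
  res <- one_way_anova(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F is invariant under affine transformation of the data", {
  set.seed(22)
  groups <- list(rnorm(5), rnorm(7, 0.5), rnorm(4, 1))
  f0 <- one_way_anova(groups)$F
  f1 <- one_way_anova(lapply(groups, function(v) 3.7 * v - 11))$F
  expect_equal(f1, f0, tolerance = 1e-10)
})

test_that("all-constant data yields an undefined F flag", {
  res <- one_way_anova(list(c(2, 2), c(2, 2, 2)))
  expect_true(res$undefined)
  expect_true(is.na(res$F))
})

test_that("well-separated groups are significant with distinct letters", {
  set.seed(23)
  a <- rnorm(5, 0, 1)
  b <- rnorm(5, 10 * 1, 1)    # ten pooled SDs apart
  tk <- tukey_kramer(list(a = a, b = b), group_names = c("a", "b"))
  expect_true(tk$pairs$significant)
  expect_setequal(unname(tk$letters), c("a", "b"))
  # oracle: q from the Kramer formula
  mse <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 8
  q_oracle <- abs(mean(a) - mean(b)) / sqrt(mse / 2 * (1 / 5 + 1 / 5))
  expect_equal(tk$pairs$q, q_oracle, tolerance = 1e-10)
  expect_equal(tk$pairs$p_adj,
               stats::ptukey(q_oracle, 2, 8, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical groups share a single letter", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  tk <- tukey_kramer(g)
  expect_false(any(tk$pairs$significant))
  expect_identical(unique(unname(tk$letters)), "a")
})

test_that("equal group sizes reduce Kramer SE to the classical Tukey HSD", {
  set.seed(24)
  groups <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2.5))
  tk <- tukey_kramer(groups)
  expect_equal(tk$pairs$se, rep(sqrt(tk$mse / 6), 3), tolerance = 1e-12)
  # cross-check adjusted p against the standard TukeyHSD implementation
  y <- unlist(groups)
  f <- factor(rep(1:3, each = 6))
  hsd <- stats::TukeyHSD(stats::aov(y ~ f))$f
  key <- c("g2-g1" = "2-1", "g3-g1" = "3-1", "g3-g2" = "3-2")
  for (i in seq_len(nrow(tk$pairs))) {
    pair <- paste0(tk$pairs$j[i], "-", tk$pairs$i[i])
    pair <- sub("g(\\d)-g(\\d)", "\\1-\\2", pair)
    expect_equal(tk$pairs$p_adj[i], hsd[pair, "p adj"], tolerance = 1e-8)
  }
})

test_that("Tukey-Kramer is symmetric under group reordering", {
  set.seed(25)
  groups <- list(a = rnorm(4), b = rnorm(6, 1), c = rnorm(5, 3))
  t1 <- tukey_kramer(groups, group_names = names(groups))
  t2 <- tukey_kramer(rev(groups), group_names = rev(names(groups)))
  p1 <- t1$pairs; p2 <- t2$pairs
  keyify <- function(p) {
    k <- ifelse(p$i < p$j, paste(p$i, p$j), paste(p$j, p$i))
    stats::setNames(p$p_adj, k)[order(k)]
  }
  expect_equal(keyify(p1), keyify(p2), tolerance = 1e-12)
  expect_identical(t1$letters[sort(names(t1$letters))],
                   t2$letters[sort(names(t2$letters))])
})

test_that("compact letters form a valid cover of the non-significance graph", {
  set.seed(26)
  for (rep in 1:5) {
    means <- runif(5, 0, 4)
    groups <- lapply(means, function(m) rnorm(sample(3:7, 1), m, 0.8))
    nm <- paste0("g", 1:5)
    tk <- tukey_kramer(groups, group_names = nm)
    share <- function(a, b) {
      any(strsplit(tk$letters[a], "")[[1]] %in%
            strsplit(tk$letters[b], "")[[1]])
    }
    for (i in seq_len(nrow(tk$pairs))) {
      pi <- tk$pairs$i[i]; pj <- tk$pairs$j[i]
      if (tk$pairs$significant[i]) {
        expect_false(share(pi, pj), label = sprintf("rep %d %s-%s", rep, pi, pj))
      } else {
        expect_true(share(pi, pj), label = sprintf("rep %d %s-%s", rep, pi, pj))
      }
    }
  }
})

test_that("groups of size one are rejected where variance is needed", {
  expect_error(tukey_kramer(list(c(1, 2), 3)), "at least 2")
})

test_that("category summary aggregates ratios by ion class", {
  set.seed(27)
  salts <- c("KNO3", "KCl", "CaCl2", "MgCl2", "CdCl2", "NiCl2", "NaCl", "AgNO3")
  cats <- assign_ion_categories(salts)
  res <- do.call(rbind, lapply(salts, function(s) {
    k <- if (cats$cation_category[cats$salt_name == s] == "heavy_metal") {
      rnorm(3, 1.2, 0.2)
    } else rnorm(3, 4.5, 0.4)
    data.frame(salt_name = s, role = "plant", ratio = k)
  }))
  out <- category_uptake_summary(res, cats, ion = "cation")
  expect_false(out$anova$undefined)
  expect_true(out$anova$p < 0.01)
  s <- out$summary
  expect_true(s$mean[s$category == "heavy_metal"] <
                min(s$mean[s$category != "heavy_metal"]))
  # heavy metals significantly below the nutrient categories: disjoint letters
  hm <- s$letter[s$category == "heavy_metal"]
  expect_false(any(grepl(hm, s$letter[s$category %in%
                                        c("macronutrient", "secondary_nutrient")])))
})
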