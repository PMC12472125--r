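coarse_fixture <- function(seq = "GGCAUGGC") {
  hx <- make_helix(seq)
  list(s = coarse_grain(hx$structure), ss = hx$ss)
}

test_that("static edges enumerate the stated bond set", {
  hx <- make_helix("GGG")
  cg <- coarse_grain(hx$structure)
  # single interior residue (has P): 5 intraresidue covalent edges
  one <- subset_residues(cg, 2)
  e1 <- build_static_edges(one)
  expect_equal(nrow(e1), 5L)
  expect_true(all(e1$class == "covalent"))
  nm <- one$atoms$atom
  keys <- sort(paste(pmin(nm[e1$i], nm[e1$j]), pmax(nm[e1$i], nm[e1$j])))
  expect_equal(keys, sort(c("C4' P", "C4' N9", "C2 N9", "C2 C6", "C6 N9")))
  # two consecutive residues add one backbone link
  two <- subset_residues(cg, 2:3)
  e2 <- build_static_edges(two)
  expect_equal(nrow(e2), 11L)   # 2 x 5 intra + 1 backbone
  # full-atom input is rejected
  expect_error(build_static_edges(hx$structure), "coarse")
})

test_that("each canonical pair contributes exactly two pairing edges", {
  fx <- coarse_fixture("GGCA")
  e <- build_static_edges(fx$s, fx$ss)
  expect_equal(sum(e$class == "pairing"), 8L)
  expect_error(build_static_edges(fx$s, new_rna_ss(cbind(0, 50), 51)),
               "out of range")
})

test_that("dynamic edges obey the distance gates", {
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  e <- build_dynamic_edges(two)
  expect_equal(e$class, "local")
  expect_equal(e$d, 4)
  e2 <- build_dynamic_edges(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(e2$class, "global")
  e3 <- build_dynamic_edges(matrix(c(0, 0, 0, 20, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(nrow(e3), 0L)
  expect_error(build_dynamic_edges(two[1, , drop = FALSE]), "at least 2")
})

test_that("the per-class neighbour cap limits dense packings to 20", {
  set.seed(8)
  # 24 satellites on a 4.9 A sphere around a central atom
  u <- matrix(rnorm(72), 24, 3)
  u <- 4.9 * u / sqrt(rowSums(u^2))
  coords <- rbind(c(0, 0, 0), u)
  e <- build_dynamic_edges(coords)
  loc <- e[e$class == "local", ]
  deg1 <- sum(loc$i == 1 | loc$j == 1)
  expect_equal(deg1, 20L)
})

test_that("edge geometry matches a direct vector-algebra oracle", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  edges <- data.frame(i = c(1, 2), j = c(2, 3),
                      class = "covalent", stringsAsFactors = FALSE)
  g <- edge_geometry(edges, coords)
  # directed edge 2 -> 1: other close neighbour of 2 is 3, collinear
  e21 <- which(g$dir_edges$src == 2 & g$dir_edges$dst == 1)
  expect_equal(g$theta[[e21]], pi)
  right <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0))
  gr <- edge_geometry(edges, right)
  er <- which(gr$dir_edges$src == 2 & gr$dir_edges$dst == 1)
  expect_equal(gr$theta[[er]], pi / 2)
  # random 4-atom chain: compare every theta and phi against acos oracle
  set.seed(12)
  ch <- matrix(rnorm(12), 4, 3)
  edges4 <- data.frame(i = 1:3, j = 2:4, class = "covalent",
                       stringsAsFactors = FALSE)
  g4 <- edge_geometry(edges4, ch)
  ang <- function(u, v) acos(max(-1, min(1,
    sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  de <- g4$dir_edges
  for (e in seq_len(nrow(de))) {
    j <- de$src[e]; i <- de$dst[e]
    nbr <- setdiff(c(de$dst[de$src == j]), i)
    th_o <- vapply(nbr, function(k) ang(ch[i, ] - ch[j, ], ch[k, ] - ch[j, ]),
                   numeric(1))
    expect_equal(sort(g4$theta[[e]]), sort(th_o), tolerance = 1e-9)
    ph_o <- numeric(0)
    for (k in nbr) for (m in setdiff(de$dst[de$src == k], j))
      ph_o <- c(ph_o, ang(ch[i, ] - ch[j, ], ch[m, ] - ch[k, ]))
    expect_equal(sort(g4$phi[[e]]), sort(ph_o), tolerance = 1e-9)
  }
  # coincident atoms are an error
  expect_error(edge_geometry(edges, coords * 0), "coincident")
})

test_that("radial basis is enveloped, finite at the origin, and orthonormal un-enveloped", {
  b <- basis_expand(5, theta = NULL, cutoff = 5)
  expect_equal(b$rbf, rep(0, 16))
  b0 <- basis_expand(1e-8, theta = NULL, cutoff = 5)
  expect_true(all(is.finite(b0$rbf)))
  bl <- basis_expand(2.5, theta = c(0.3, 1.2), cutoff = 5)
  expect_equal(dim(bl$sbf), c(7, 16))
  expect_true(all(is.finite(bl$sbf)))
  # un-enveloped sine-Bessel family: integral of b_m b_n d^2 over [0, c]
  cc <- 5
  unenv <- function(d, n) sqrt(2 / cc) * sin(n * pi * d / cc) / d
  for (m in c(1, 3)) for (n in c(1, 3, 6)) {
    val <- integrate(function(d) unenv(d, m) * unenv(d, n) * d^2, 0, cc,
                     rel.tol = 1e-10)$value
    expect_equal(val, as.numeric(m == n), tolerance = 1e-7)
  }
})

test_that("assembled graphs have the expected nodes, classes and pairing edges", {
  fx <- coarse_fixture("GGCAUGGC")
  # 3-residue single strand: 15 atoms, or 14 with the 5' P missing
  three <- subset_residues(fx$s, 1:3)
  g3 <- assemble_graph(three)
  expect_equal(g3$node_count, 15L)
  tmpl <- template_structure("GGC")
  expect_equal(nrow(tmpl$atoms), 14L)
  g <- assemble_graph(fx$s, fx$ss)
  expect_equal(g$node_count, 80L)
  # every canonical pair has its two pairing edges
  expect_equal(sum(g$edges$class == "pairing"), 2L * nrow(fx$ss$pairs))
  # local and global never coexist on one atom pair; distances respect gates
  key <- paste(g$edges$i, g$edges$j)
  dyn <- g$edges$class %in% c("local", "global")
  expect_false(any(duplicated(key[dyn])))
  expect_true(all(g$edges$d[g$edges$class == "local"] <= 5))
  expect_true(all(g$edges$d[g$edges$class == "global"] > 5 &
                    g$edges$d[g$edges$class == "global"] <= 16))
  expect_error(assemble_graph(fx$s, fx$ss,
                              seq_embeddings = matrix(0, 3, 256)),
               "embedding count")
})

test_that("graph dumps are deterministic and diffable", {
  fx <- coarse_fixture("GGCA")
  g <- assemble_graph(fx$s, fx$ss)
  dir <- withr::local_tempdir()
  graph_dump(g, file.path(dir, "a"))
  graph_dump(g, file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a_edges.tsv")),
                   readLines(file.path(dir, "b_edges.tsv")))
})

test_that("dynamic edge sets satisfy the stated invariants on random clouds", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    coords <- matrix(runif(3 * n, 0, 25), n, 3)
    e <- build_dynamic_edges(coords)
    if (nrow(e) == 0) next
    expect_true(all(e$d[e$class == "local"] <= 5))
    expect_true(all(e$d[e$class == "global"] > 5 &
                      e$d[e$class == "global"] <= 16))
    for (cl in c("local", "global")) {
      ecl <- e[e$class == cl, ]
      if (nrow(ecl) == 0) next
      expect_lte(max(table(c(ecl$i, ecl$j))), 20)
    }
    # rigid-motion invariance of the edge set
    e2 <- build_dynamic_edges(rigid_motion(coords))
    expect_equal(e[, c("i", "j", "class")], e2[, c("i", "j", "class")],
                 ignore_attr = TRUE)
    expect_equal(e$d, e2$d, tolerance = 1e-9)
  }
})
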