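test_that("diagram parsing validates structure", {
  cfg <- '[
    {"name": "tail", "kind": "bd", "gain": 1, "loss": 1},
    {"name": "color", "kind": "qualitative", "states": ["r", "b"], "parent": "tail"}
  ]'
  d <- parse_diagram(cfg)
  expect_s3_class(d, "dependency_diagram")
  expect_equal(nrow(d$arrows), 1)
  expect_equal(d$roots, "tail")
  res <- dda_traverse(d)
  expect_equal(nrow(res$Q), 3)

  bad <- '[
    {"name": "color", "kind": "qualitative", "states": ["r", "b"]},
    {"name": "tail", "kind": "bd", "parent": "color"}
  ]'
  expect_error(parse_diagram(bad), "qualitative")
  expect_error(parse_diagram('[{"name":"x","kind":"bd","parent":"nope"}]'),
               "unknown parent")
  cyc <- '[
    {"name": "x", "kind": "bd", "parent": "y"},
    {"name": "y", "kind": "bd", "parent": "x"}
  ]'
  expect_error(parse_diagram(cyc), "cycle")
})

test_that("DDA reproduces the printed dimensions and step counts", {
  # complex seven-character hierarchy: six steps, dimension 31 (big enough
  # to trigger the moderate-size advisory)
  expect_warning(res <- dda_traverse(complex_diagram()), "moderate-size")
  expect_equal(nrow(res$Q), 31)
  expect_equal(nrow(res$trace), 6)
  expect_equal(res$trace$dim_out[6], 31)
  expect_true(validate_rate_matrix(res$Q)$valid)

  # tail-colour gives the three-state matrix of the ED-ql amalgamation
  tc <- dependency_diagram(list(tail_spec(), color_spec()),
                           data.frame(from = "tail", to = "color"))
  rtc <- dda_traverse(tc)
  expect_equal(nrow(rtc$Q), 3)
  expect_equal(unclass(rtc$Q)[, ],
               unclass(ed_ql(tail_spec(), color_spec()))[, ], tolerance = 1e-12)

  # TCA: successive ED-ql then ED-bd amalgamation, 4 states
  rtca <- dda_traverse(tca_diagram())
  expect_equal(rownames(rtca$Q), c("aa1", "pa1", "pp1r", "pp1b"))
  expect_equal(rtca$trace$type, c("ED-ql", "ED-bd"))

  # single independent character: no amalgamation steps
  single <- dependency_diagram(list(color_spec()))
  rs <- dda_traverse(single)
  expect_equal(nrow(rs$Q), 2)
  expect_equal(NROW(rs$trace), 0)
})

test_that("DDA dimension follows the recursive law on random diagrams", {
  # oracle: brute-force enumeration of valid state combinations (a dependent
  # is non-absent only if all characters on its path to the root are present)
  set.seed(11)
  for (rep in 1:8) {
    n_bd <- sample(1:3, 1); n_ql <- sample(0:2, 1)
    chars <- list(char_bd("b1", 1, 1, labels = c("a1", "p1")))
    if (n_bd > 1) for (i in 2:n_bd)
      chars <- c(chars, list(char_bd(paste0("b", i), 1, 1,
                                     labels = paste0(c("a", "p"), i))))
    if (n_ql > 0) for (i in seq_len(n_ql)) {
      k <- sample(2:3, 1)
      chars <- c(chars, list(char_ql(paste0("q", i),
        rate_matrix(matrix(1, k, k) - diag(k, k),
                    labels = paste0("s", i, seq_len(k)), fix_diagonal = TRUE))))
    }
    nms <- vapply(chars, `[[`, "", "name")
    bd_names <- nms[startsWith(nms, "b")]
    arrows <- NULL
    for (nm in nms[-1]) {
      cand <- setdiff(bd_names, nm)
      # attach anywhere earlier in the list to stay acyclic
      cand <- cand[match(cand, nms) < match(nm, nms)]
      if (length(cand) && stats::runif(1) < 0.8)
        arrows <- rbind(arrows, data.frame(from = sample(cand, 1), to = nm))
    }
    d <- dependency_diagram(chars, arrows)
    res <- suppressWarnings(dda_traverse(d, combine_independent = TRUE))
    # enumeration oracle over per-character state assignments
    ctrl <- setNames(rep(NA_character_, length(nms)), nms)
    if (!is.null(arrows)) ctrl[arrows$to] <- arrows$from
    statesets <- lapply(chars, function(ch) ch$labels)
    names(statesets) <- nms
    grid <- do.call(expand.grid, c(statesets, stringsAsFactors = FALSE))
    valid <- 0
    for (r in seq_len(nrow(grid))) {
      ok <- TRUE
      for (nm in nms) {
        up <- ctrl[[nm]]
        applicable <- TRUE
        while (!is.na(up)) {  # walk controllers to the root
          if (grid[r, up] != chars[[match(up, nms)]]$labels[2]) applicable <- FALSE
          up <- ctrl[[up]]
        }
        val <- grid[r, nm]
        is_absentish <- val == chars[[match(nm, nms)]]$labels[1]
        if (!applicable && chars[[match(nm, nms)]]$kind == "qualitative") {
          # qualitative states are inapplicable wholesale: any value invalid,
          # the combination is only counted once via the canonical first state
          if (val != chars[[match(nm, nms)]]$labels[1]) ok <- FALSE
        } else if (!applicable && !is_absentish) ok <- FALSE
      }
      if (ok) valid <- valid + 1
    }
    expect_equal(nrow(res$Q), valid)
  }
})

test_that("recoding maps hierarchy columns onto amalgamated states", {
  d <- tca_diagram()
  data <- character_matrix(rbind(
    t1 = c(tail = "a", armor = "-", color = "-"),
    t2 = c(tail = "p", armor = "a1", color = "-"),
    t3 = c(tail = "p", armor = "p1", color = "r"),
    t4 = c(tail = "p", armor = "p1", color = "?"),
    t5 = c(tail = "?", armor = "?", color = "?")))
  rc <- recode_characters(data, d)
  expect_equal(unname(rc[, 1]),
               c("aa1", "pa1", "pp1r", "pp1r/pp1b", "aa1/pa1/pp1r/pp1b"))

  # contradiction: controller absent but dependent applicable
  bad <- character_matrix(rbind(t1 = c(tail = "a", armor = "-", color = "b")))
  colnames(bad) <- c("tail", "armor", "color")
  expect_error(recode_characters(bad, d), "contradictory.*t1")

  # recode of decode is the identity on consistent full rows
  dda <- attr(rc, "dda")
  for (s in rownames(dda$Q)) {
    dec <- decode_state(s, dda)
    row <- character_matrix(matrix(dec, 1, dimnames = list("x", names(dec))))
    expect_equal(unname(recode_characters(row, d)[1, 1]), s)
  }
})
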