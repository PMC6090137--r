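all_zero_grades <- function() {
  strains <- fbi_strains()
  kng <- setNames(strains$kingdom, strains$strain)
  tidyr::expand_grid(focal = strains$strain, partner = strains$strain,
                     medium = c("CP", "LB", "MM", "PDA")) |>
    dplyr::filter(kng[focal] != kng[partner]) |>
    dplyr::mutate(kingdom = unname(kng[focal]), d3 = 0L, d5 = 0L, d7 = 0L,
                  grade = 0L, label = "none", mixed = FALSE, status = "ok")
}

test_that("eight roster-ordered rectangular networks are built", {
  nets <- build_networks(all_zero_grades(), strains = fbi_strains())
  expect_equal(nrow(nets), 8)
  expect_setequal(nets$direction, c("fungi_to_bacteria", "bacteria_to_fungi"))
  f2b <- nets$network[[which(nets$direction == "fungi_to_bacteria")[1]]]
  b2f <- nets$network[[which(nets$direction == "bacteria_to_fungi")[1]]]
  expect_equal(dim(f2b$weights), c(4, 5))
  expect_equal(dim(b2f$weights), c(5, 4))
  expect_identical(rownames(f2b$weights), paste0("F", 1:4))
  expect_identical(colnames(f2b$weights), paste0("B", 1:5))
  expect_true(all(purrr::map_lgl(nets$network, ~ all(.x$weights == 0))))
})

test_that("grades land on the correct source-to-target cell", {
  grades <- all_zero_grades() |>
    dplyr::mutate(grade = ifelse(focal == "B3" & partner == "F2" & medium == "MM",
                                 4L, grade))
  nets <- build_networks(grades, strains = fbi_strains())
  mm_f2b <- nets$network[[which(nets$medium == "MM" &
                                  nets$direction == "fungi_to_bacteria")]]
  expect_equal(mm_f2b$weights["F2", "B3"], 4)
  expect_equal(sum(mm_f2b$weights != 0), 1)
  mm_b2f <- nets$network[[which(nets$medium == "MM" &
                                  nets$direction == "bacteria_to_fungi")]]
  expect_true(all(mm_b2f$weights == 0))  # directions are independent objects
})

test_that("connectivity is the percentage of realised links", {
  w <- matrix(0L, 4, 5)
  net0 <- fbinet:::new_fbi_network("MM", "fungi_to_bacteria",
                                   paste0("F", 1:4), paste0("B", 1:5), w)
  expect_equal(connectivity(net0), 0)
  w[seq_len(11)] <- 3L
  net11 <- fbinet:::new_fbi_network("MM", "fungi_to_bacteria",
                                    paste0("F", 1:4), paste0("B", 1:5), w)
  expect_equal(connectivity(net11), 55)
  w[] <- -2L
  expect_equal(connectivity(fbinet:::new_fbi_network(
    "MM", "fungi_to_bacteria", paste0("F", 1:4), paste0("B", 1:5), w)), 100)
  # strictly monotone in the number of links
  conn <- vapply(0:20, function(k) {
    w <- matrix(0L, 4, 5); w[seq_len(k)] <- 1L
    connectivity(fbinet:::new_fbi_network("MM", "fungi_to_bacteria",
                                          paste0("F", 1:4), paste0("B", 1:5), w))
  }, numeric(1))
  expect_true(all(diff(conn) > 0))
})

test_that("networks round-trip through edge CSV and GraphML", {
  set.seed(31)
  strains <- fbi_strains()
  fungi <- paste0("F", 1:4); bacteria <- paste0("B", 1:5)
  nets <- tibble::tibble(
    medium = rep(c("MM", "PDA"), each = 2),
    direction = rep(c("fungi_to_bacteria", "bacteria_to_fungi"), 2)
  )
  nets$network <- purrr::map2(nets$medium, nets$direction, function(m, d) {
    if (d == "fungi_to_bacteria") {
      fbinet:::new_fbi_network(m, d, fungi, bacteria,
                               matrix(sample(-6:6, 20, TRUE), 4))
    } else {
      fbinet:::new_fbi_network(m, d, bacteria, fungi,
                               matrix(sample(-6:6, 20, TRUE), 5))
    }
  })

  csv_all <- withr::local_tempfile(fileext = ".csv")
  write_network_edges(nets, csv_all)
  edges <- readr::read_csv(csv_all, show_col_types = FALSE)
  expect_equal(nrow(edges),
               sum(purrr::map_int(nets$network, ~ sum(.x$weights != 0))))

  # the edge CSV stores links only, so rebuilding needs one roster
  # orientation at a time
  f2b <- nets[nets$direction == "fungi_to_bacteria", ]
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network_edges(f2b, csv)
  back <- read_network_edges(csv, sources = fungi, targets = bacteria)
  for (i in seq_len(nrow(f2b))) {
    orig <- f2b$network[[i]]
    match_row <- which(back$medium == orig$medium &
                         back$direction == orig$direction)
    expect_identical(back$network[[match_row]]$weights, orig$weights)
  }

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(nets$network[[1]], gml)
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")
  rt <- read_network_graphml(gml)
  expect_identical(rt$weights, nets$network[[1]]$weights)
  expect_identical(rt$medium, nets$network[[1]]$medium)

  # an edgeless network still round-trips its node rosters
  empty <- fbinet:::new_fbi_network("LB", "fungi_to_bacteria", fungi, bacteria,
                                    matrix(0L, 4, 5))
  write_network_graphml(empty, gml)
  rt0 <- read_network_graphml(gml)
  expect_identical(rt0$weights, empty$weights)
})

test_that("malformed grade tables are rejected", {
  grades <- all_zero_grades()
  expect_error(build_networks(grades, strains = fbi_strains(n_fungi = 3)),
               "outside the roster")
  incomplete <- grades[-1, ]
  expect_error(build_networks(incomplete, strains = fbi_strains()), "expected")
  flagged <- dplyr::mutate(grades,
                           status = ifelse(dplyr::row_number() == 1,
                                           "incomplete", status))
  expect_error(build_networks(flagged, strains = fbi_strains()), "incomplete")
})

test_that("the network edge tibble and plot reflect the weight matrix", {
  w <- matrix(0L, 4, 5); w[1, 2] <- 6L; w[3, 4] <- -3L
  net <- fbinet:::new_fbi_network("MM", "fungi_to_bacteria",
                                  paste0("F", 1:4), paste0("B", 1:5), w)
  tb <- tibble::as_tibble(net)
  expect_equal(nrow(tb), 20)
  expect_equal(tb$grade[tb$source == "F1" & tb$target == "B2"], 6)
  expect_equal(tb$sign[tb$source == "F3" & tb$target == "B4"], -1)
  p <- ggplot2::autoplot(net)
  expect_s3_class(p, "ggplot")
})
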