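cfg <- default_config()

test_that("initial subsections split bundles at extended linkers", {
  two <- assign_sse(make_monomer(2, 40, seed = 3))
  iv <- initial_subsections(two, cfg)
  expect_equal(nrow(iv), 2)
  one <- assign_sse(make_monomer(1, 40, seed = 3))
  expect_equal(nrow(initial_subsections(one, cfg)), 1)
  ## helix-turn-helix with dense contacts stays one interval when the
  ## segment pair shares at least k_link contacts (oracle-checked)
  n <- contact_count(two, residue_selection(two, resno = 1:12),
                     residue_selection(two, resno = 13:24),
                     cutoff = cfg$contact_cutoff)
  expect_gte(n, cfg$k_link)   # consecutive helices of one bundle crosslink
  expect_warning(
    iv_coil <- initial_subsections(assign_sse(build_peptide(30, -139, 135)),
                                   cfg), "all-coil")
  expect_equal(nrow(iv_coil), 1)
})

test_that("merging reaches saturation at the planted domain structure", {
  m <- assign_sse(make_monomer(2, 40, seed = 3))
  iv <- initial_subsections(m, cfg)
  part <- merge_to_domains(m, iv, cfg)
  expect_equal(nrow(part$intervals), 2)
  ## artificially split one blob: merging heals the split
  one <- assign_sse(make_monomer(1, 40, seed = 4))
  rn <- chain_resnos(one, "A")
  split <- data.frame(start = c(min(rn), 21), end = c(20, max(rn)))
  healed <- merge_to_domains(one, split, cfg)
  expect_equal(nrow(healed$intervals), 1)
  ## idempotence: re-running on its own output changes nothing
  again <- merge_to_domains(m, part$intervals, cfg)
  expect_equal(again$intervals, part$intervals)
})

test_that("planted k-blob monomers are recovered for k = 1..5", {
  for (k in 1:5) {
    m <- assign_sse(make_monomer(k, 36, seed = 10 + k))
    part <- merge_to_domains(m, initial_subsections(m, cfg), cfg)
    expect_equal(nrow(part$intervals), k, label = paste("k =", k))
    ## coverage and disjointness
    iv <- part$intervals
    expect_true(all(diff(iv$start) > 0))
    if (k > 1) expect_true(all(iv$start[-1] > iv$end[-k]))
    covered <- sum(iv$end - iv$start + 1)
    expect_gte(covered / length(chain_resnos(m, "A")), 0.9)
  }
})

test_that("linker cropping minimizes cross-contacts (exhaustive oracle)", {
  m <- assign_sse(make_monomer(2, 40, seed = 6))
  part <- merge_to_domains(m, initial_subsections(m, cfg), cfg)
  cropped <- crop_linkers(m, part, cfg)
  b <- cropped$intervals$end[1]
  ## oracle: scan every coil cut position, expect the chosen cut minimal
  lab <- m$sse$A; rn <- as.integer(names(lab))
  sel <- function(a, b2) residue_selection(m, chain = "A", resno = a:b2)
  coil <- rn[lab == "C" & rn >= part$intervals$start[1] &
               rn < part$intervals$end[2]]
  coil <- coil[coil >= 30 & coil <= 70]     # the inter-domain stretch
  cross <- vapply(coil, function(cut) contact_count(
    m, sel(part$intervals$start[1], cut),
    sel(cut + 1, part$intervals$end[2]), cfg$contact_cutoff), numeric(1))
  expect_equal(min(cross),
               contact_count(m, sel(cropped$intervals$start[1], b),
                             sel(b + 1, cropped$intervals$end[2]),
                             cfg$contact_cutoff))
  expect_error(crop_linkers(m, structure(list(
    intervals = data.frame(start = 1, end = 100), chain = "A"),
    class = "domain_partition"), cfg), ">= 2 domains")
})

test_that("five-subchain scheme follows the domain-count thirds", {
  part6 <- structure(list(intervals = data.frame(
    start = seq(1, 501, 100), end = seq(100, 600, 100)), chain = "A"),
    class = "domain_partition")
  sub <- make_subchains(part6, chain_len = 600, config = cfg)
  expect_equal(nrow(sub), 5)
  expect_equal(sub$start[sub$id == "full"], 1)
  expect_equal(sub$end[sub$id == "full"], 600)
  expect_equal(sub$start[sub$id == "no_nterm"], 101)
  expect_equal(sub$end[sub$id == "no_cterm"], 500)
  expect_equal(unname(unlist(sub[sub$id == "first_third", c("start", "end")])),
               c(1, 200))
  expect_equal(unname(unlist(sub[sub$id == "last_third", c("start", "end")])),
               c(401, 600))
  ## 3 domains: first third = domain 1 (clamped to the minimum length)
  part3 <- structure(list(intervals = data.frame(
    start = c(1, 201, 401), end = c(200, 400, 600)), chain = "A"),
    class = "domain_partition")
  sub3 <- make_subchains(part3, 600, cfg)
  expect_equal(sub3$end[sub3$id == "first_third"], 200)
  expect_equal(sub3$start[sub3$id == "first_third"], 1)
  ## 1 domain: degenerate, flagged
  part1 <- structure(list(intervals = data.frame(start = 1, end = 300),
                          chain = "A"), class = "domain_partition")
  expect_warning(sub1 <- make_subchains(part1, 300, cfg), "single-domain")
  expect_equal(nrow(sub1), 1)
  expect_true(attr(sub1, "single_domain"))
})

test_that("subchain lengths are clamped and duplicates collapse", {
  ## tiny domains: every subchain stretched to the minimum length
  part <- structure(list(intervals = data.frame(
    start = c(1, 51, 101), end = c(50, 100, 150)), chain = "A"),
    class = "domain_partition")
  expect_warning(sub <- make_subchains(part, 150, cfg), "collapsed")
  expect_true(all(sub$end - sub$start + 1 >= min(cfg$subchain_min_len, 150)))
  expect_false(any(duplicated(sub[, c("start", "end")])))
})

test_that("p1 single-domain specs mirror the partition", {
  part4 <- structure(list(intervals = data.frame(
    start = c(301, 1, 101, 201), end = c(400, 100, 200, 300)), chain = "A"),
    class = "domain_partition")
  specs <- p1_single_domains(part4)
  expect_equal(nrow(specs), 4)
  expect_equal(specs$start, c(1, 101, 201, 301))   # sorted by start
  expect_equal(specs$end, c(100, 200, 300, 400))
  expect_match(specs$id, "^single_domain:")
  part1 <- structure(list(intervals = data.frame(start = 1, end = 100),
                          chain = "A"), class = "domain_partition")
  expect_error(p1_single_domains(part1), "standard subchain")
})

test_that("domain FASTA encodes boundaries as line breaks", {
  m <- make_monomer(2, 24, seed = 8)
  part <- structure(list(intervals = attr(m, "domains"), chain = "A"),
                    class = "domain_partition")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_domain_fasta(m, part, path, name = "toy")
  back <- read_domain_fasta(path)
  expect_equal(nrow(back$intervals), 2)
  expect_equal(back$intervals$end[1] - back$intervals$start[1] + 1, 24)
})
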