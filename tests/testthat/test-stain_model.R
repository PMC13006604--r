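# Stain model: intensity averaging and additive/physical rendering.

test_that("intensity stack averages assigned channels and handles degenerate classes", {
  p1 <- rand_matrix(8, seed = 11)
  p2 <- rand_matrix(8, seed = 12)
  img <- multiplex_image(list(A = p1, B = p2))
  prof <- stain_profile("s", list(
    stain_class("one", c(0, 0, 0), markers = "a"),
    stain_class("two", c(0, 0, 0), markers = c("a", "b")),
    stain_class("empty", c(0, 0, 0), markers = character())
  ))
  asn <- channel_assignment(list(one = "A", two = c("A", "B"),
                                 empty = character()))
  st <- compute_intensity_stack(img, asn, prof)
  expect_identical(st$planes$one, p1)            # single marker: identity
  expect_equal(st$planes$two, (p1 + p2) / 2)     # arithmetic mean
  expect_identical(st$planes$empty, matrix(0, 8, 8))
  # scalar check: 0.2 and 0.6 average to 0.4
  img2 <- multiplex_image(list(A = matrix(0.2, 2, 2), B = matrix(0.6, 2, 2)))
  st2 <- compute_intensity_stack(img2, channel_assignment(
    list(one = "A", two = c("A", "B"), empty = character())), prof)
  expect_equal(st2$planes$two[1, 1], 0.4)
})

test_that("unknown assigned channel errors naming channel and class", {
  img <- multiplex_image(list(A = matrix(0.5, 2, 2)))
  prof <- one_class_profile()
  expect_error(
    compute_intensity_stack(img, channel_assignment(list(a = "NOPE")), prof),
    "NOPE.*class 'a'"
  )
})

test_that("zero intensities render to the background in both methods", {
  prof <- one_class_profile(color = c(0.3, 0.4, 0.5))
  st <- stack_of(a = matrix(0, 4, 4))
  for (m in c("additive", "physical")) {
    r <- render(st, prof, render_settings(background = c(0.9, 0.8, 0.7),
                                          method = m))
    for (c in 1:3) {
      expect_equal(unique(as.vector(r$data[, , c])), c(0.9, 0.8, 0.7)[c])
    }
  }
})

test_that("single-class closed form: physical e^-1, additive 0", {
  prof <- one_class_profile(color = c(0, 0, 0), scaling = 1)
  st <- stack_of(a = matrix(1, 3, 3))
  phys <- render(st, prof, render_settings(method = "physical"))
  addi <- render(st, prof, render_settings(method = "additive"))
  expect_equal(as.vector(phys$data), rep(exp(-1), 27), tolerance = 1e-12)
  expect_equal(as.vector(addi$data), rep(0, 27))
})

test_that("stain color equal to background leaves that channel unattenuated", {
  prof <- one_class_profile(color = c(1, 0, 0))  # S_R = c_R
  st <- stack_of(a = rand_matrix(6, seed = 4))
  for (m in c("additive", "physical")) {
    r <- render(st, prof, render_settings(method = m))
    expect_equal(unique(as.vector(r$data[, , 1])), 1)
  }
})

test_that("physical output decreases monotonically to the floor as exponent grows", {
  prof <- one_class_profile(color = c(0.2, 0.2, 0.2))
  floor_v <- c(0.1, 0.05, 0)
  settings <- render_settings(floor = floor_v, method = "physical")
  vals <- vapply(c(0.5, 1, 2, 5, 20, 100), function(k) {
    p <- one_class_profile(color = c(0.2, 0.2, 0.2), scaling = k)
    render(stack_of(a = matrix(1, 1, 1)), p, settings)$data[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[length(vals)], floor_v[1], tolerance = 1e-12)
})

test_that("brighter-than-background stain colors are clamped with a warning", {
  prof <- one_class_profile(color = c(0.5, 0.5, 0.5))
  st <- stack_of(a = matrix(1, 2, 2))
  s <- render_settings(background = c(0.4, 1, 1), method = "physical")
  expect_warning(r <- render(st, prof, s), "clamped")
  expect_equal(unique(as.vector(r$data[, , 1])), 0.4)  # no brightening
})

test_that("physical >= additive pixelwise with white background and zero floor", {
  for (seed in 1:10) {
    set.seed(seed)
    prof <- stain_profile("s", list(
      stain_class("a", runif(3, 0, 0.9), scaling = runif(1, 0.2, 2), markers = "x"),
      stain_class("b", runif(3, 0, 0.9), scaling = runif(1, 0.2, 2), markers = "y")
    ))
    st <- stack_of(a = rand_matrix(8, seed = seed), b = rand_matrix(8, seed = seed + 100))
    p <- render(st, prof, render_settings(method = "physical"))
    a <- render(st, prof, render_settings(method = "additive"))
    expect_true(all(p$data >= a$data - 1e-12))
  }
})

test_that("additive-physical gap obeys the quadratic linearization bound", {
  # scalar model with white background, zero floor: gap = e^-x - (1-x) <= x^2/2
  set.seed(42)
  x <- runif(200, 0, 0.5)
  prof <- one_class_profile(color = c(0, 0, 0))
  st <- stack_of(a = matrix(x, 10, 20))
  gap <- render(st, prof, render_settings(method = "physical"))$data[, , 1] -
    render(st, prof, render_settings(method = "additive"))$data[, , 1]
  expect_true(all(gap >= 0))
  expect_true(all(gap <= matrix(x, 10, 20)^2 / 2 + 1e-12))
})

test_that("joint rendering multiplies per-class transmission factors", {
  # with zero floor the physical exponent is additive over classes
  pa <- rand_matrix(6, seed = 21); pb <- rand_matrix(6, seed = 22)
  cls_a <- stain_class("a", c(0.3, 0.5, 0.1), scaling = 0.8, markers = "x")
  cls_b <- stain_class("b", c(0.6, 0.2, 0.4), scaling = 1.3, markers = "y")
  joint <- render(stack_of(a = pa, b = pb),
                  stain_profile("j", list(cls_a, cls_b)),
                  render_settings(method = "physical"))
  only_a <- render(stack_of(a = pa), stain_profile("a", list(cls_a)),
                   render_settings(method = "physical"))
  only_b <- render(stack_of(b = pb), stain_profile("b", list(cls_b)),
                   render_settings(method = "physical"))
  expect_equal(joint$data, only_a$data * only_b$data, tolerance = 1e-12)
})

test_that("volume rendering equals slice-wise 2D rendering and passes spacing", {
  set.seed(7)
  nz <- 3
  ch <- list(DNA1 = array(runif(64 * nz), c(8, 8, nz)),
             Vimentin = array(runif(64 * nz), c(8, 8, nz)))
  ch$DNA1[, , 2] <- 0; ch$Vimentin[, , 2] <- 0  # slice 2 empty
  vol <- multiplex_image(ch, pixel_size_um = 1, slice_spacing_um = 25)
  prof <- stain_preset("h_and_e")
  slices <- render_volume(vol, prof)
  expect_length(slices, nz)
  expect_equal(attr(slices, "slice_spacing_um"), 25)
  for (s in seq_len(nz)) {
    img2d <- multiplex_image(lapply(ch, function(p) p[, , s]))
    expect_equal(slices[[s]]$data, render_multiplex(img2d, prof)$data)
  }
  # empty slice renders to uniform background
  expect_equal(unique(as.vector(slices[[2]]$data)), 1)
})

test_that("permuting slice order permutes rendered slices identically", {
  set.seed(8)
  ch <- list(DNA1 = array(runif(32 * 3), c(4, 8, 3)))
  vol <- multiplex_image(ch)
  prof <- stain_preset("h_and_e")
  fwd <- render_volume(vol, prof)
  perm <- c(3, 1, 2)
  vol2 <- multiplex_image(list(DNA1 = ch$DNA1[, , perm]))
  rev <- render_volume(vol2, prof)
  for (s in 1:3) expect_equal(rev[[s]]$data, fwd[[perm[s]]]$data)
})

test_that("mismatched plane counts are rejected", {
  prof <- stain_profile("s", list(stain_class("a", c(0, 0, 0), markers = "x"),
                                  stain_class("b", c(0, 0, 0), markers = "y")))
  expect_error(render(stack_of(a = matrix(0, 2, 2)), prof,
                      render_settings()), "planes")
})
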