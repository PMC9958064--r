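test_that("MBConv fragments follow the conv -> BN -> swish entry pattern", {
  frag <- build_mbconv("MBConv-A", 32, 16, 2)
  kinds <- vapply(frag$nodes, `[[`, "", "kind")[1:3]
  expect_identical(unname(kinds), c("conv", "batchnorm", "activation"))
  head <- frag$nodes[[1]]
  expect_identical(head$kernel_size, 3L)
  expect_identical(head$stride, 2L)
  expect_identical(frag$nodes[[3]]$activation, "swish")
  # ends in the SE gate followed by a swish
  last <- frag$nodes[[length(frag$nodes)]]
  expect_identical(last$activation, "swish")
  expect_identical(frag$nodes[[last$inputs]]$kind, "multiply")
  expect_error(build_mbconv("MBConv-C", 8, 8), "variant")
})

test_that("stride-1 MBConv preserves spatial size; stride-2 halves it", {
  gB <- as_model_graph(build_mbconv("MBConv-B", 3, 8, se_reduction = 2),
                       input_size = 40)
  expect_identical(graph_shapes(gB)[[gB$output]], c(40L, 40L, 8L))
  gA <- as_model_graph(build_mbconv("MBConv-A", 3, 8, se_reduction = 2),
                       input_size = 40)
  expect_identical(graph_shapes(gA)[[gA$output]], c(20L, 20L, 8L))
})

test_that("MBConv parameter count matches independent tensor enumeration", {
  g <- as_model_graph(build_mbconv("MBConv-A", 8, 8, 1), input_size = 32,
                      input_channels = 8)
  # hand count: conv 9*8*8+8, bn 16, dw 9*8+8, bn 16, se 8*2+2 + 2*8+8
  expect_identical(count_params(g), 584 + 16 + 80 + 16 + 18 + 24)
  expect_identical(count_params(g), enumerate_params(g))
})

test_that("SE block squeezes by the reduction ratio and gates channels", {
  frag <- build_se_block(32, 4)
  squeeze <- frag$nodes[["squeeze"]]
  expect_identical(squeeze$out_channels, 8L)
  expect_error(build_se_block(8, 16), "squeeze")
  # a saturated sigmoid gate (weights 0, large bias) passes input through
  g <- as_model_graph(build_se_block(4, 2), input_size = 8,
                      input_channels = 4)
  m <- init_model(g, seed = 1)
  m$params$squeeze$W[] <- 0
  m$params$expand$W[] <- 0
  m$params$expand$b[] <- 100  # sigmoid(100) == 1
  x <- array(runif(8 * 8 * 4 * 2), dim = c(8, 8, 4, 2))
  fw <- cenkd:::forward_pass(m, x, train = FALSE)
  expect_equal(fw$out, x, tolerance = 1e-12)
})

test_that("CEN stays within the 20K parameter budget and is deep-greedy", {
  g <- build_cen(224)
  expect_lte(count_params(g), 20000)
  expect_identical(count_params(g), enumerate_params(g))
  # adding the next whole block in the plan would exceed the budget
  next_block <- build_mbconv("MBConv-A", 24, 40, 2)
  frag_cost <- sum(vapply(next_block$nodes, cenkd:::node_param_count, 0))
  expect_gt(count_params(g) + frag_cost, 20000)
  expect_error(build_cen(16), "too small")
})

test_that("model initialization is bit-reproducible given a seed", {
  g <- build_cen(64)
  m1 <- init_model(g, seed = 11)
  m2 <- init_model(g, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(g, seed = 12)
  expect_false(identical(m1$params$stem_conv$W, m3$params$stem_conv$W))
})

test_that("fuse is element-wise addition with identity and symmetry", {
  expect_equal(fuse(c(1, 2), c(3, 4)), c(4, 6))
  f <- array(rnorm(24), dim = c(2, 2, 3, 2))
  expect_equal(fuse(f, array(0, dim(f))), f)
  expect_equal(fuse(f, f), 2 * f)
  g <- array(rnorm(24), dim = dim(f))
  h <- array(rnorm(24), dim = dim(f))
  expect_equal(fuse(f, g), fuse(g, f))
  expect_equal(fuse(fuse(f, g), h), fuse(f, fuse(g, h)))
  expect_error(fuse(matrix(0, 2, 2), matrix(0, 2, 3)), "shape mismatch")
})

test_that("MRSB uses only 1x1 depthwise + pointwise layers", {
  frag <- build_mrsb(64)
  kinds <- vapply(frag$nodes, `[[`, "", "kind")
  expect_identical(sum(kinds == "dwconv"), 1L)
  expect_identical(sum(kinds == "pwconv"), 1L)
  expect_identical(sum(kinds == "conv"), 0L)
  ks <- vapply(frag$nodes, `[[`, 1L, "kernel_size")
  expect_true(all(ks == 1L))
  # hand count for 64 channels: dw 64+64, pw 64*64+64
  g <- as_model_graph(frag, input_size = 32, input_channels = 64)
  expect_identical(count_params(g), 128 + 64 * 64 + 64)
  expect_identical(count_params(g), enumerate_params(g))
})

test_that("MRSB with a zeroed main branch is the identity map", {
  g <- as_model_graph(build_mrsb(8), input_size = 32, input_channels = 8)
  m <- init_model(g, seed = 5)
  m$params$dw$W[] <- 0
  m$params$dw$b[] <- 0
  m$params$pw$W[] <- 0
  m$params$pw$b[] <- 0
  x <- array(rnorm(32 * 32 * 8 * 3), dim = c(32, 32, 8, 3))
  fw <- cenkd:::forward_pass(m, x, train = FALSE)
  expect_equal(fw$out, x, tolerance = 1e-12)
})

test_that("attach_head appends GAP/dense/softmax and keeps logits", {
  g <- attach_head(build_cen(64), 6)
  expect_identical(g$nodes[["head_dense"]]$units, 6L)
  expect_identical(g$logits, "head_dense")
  expect_identical(g$nodes[[g$output]]$activation, "softmax")
  backbone <- build_cen(64)
  c_out <- graph_shapes(backbone)[[backbone$output]][3]
  expect_identical(count_params(g) - count_params(backbone),
                   (c_out + 1) * 6)
  expect_error(attach_head(build_cen(64), 1), "num_classes")
})

test_that("student branches share architecture but not weights", {
  g <- build_student(64, 6, seed = 2)
  m <- init_model(g)
  expect_identical(dim(m$params$cen1_stem_conv$W),
                   dim(m$params$cen2_stem_conv$W))
  expect_false(identical(m$params$cen1_stem_conv$W,
                         m$params$cen2_stem_conv$W))
  # sum of parts: 2 x CEN + MRSB + head
  cen <- build_cen(64)
  c_out <- graph_shapes(cen)[[cen$output]][3]
  mrsb <- count_params(as_model_graph(build_mrsb(c_out), input_size = 32,
                                      input_channels = c_out))
  head <- (c_out + 1) * 6
  expect_identical(count_params(g), 2L * count_params(cen) + mrsb + head)
  expect_identical(count_params(g), enumerate_params(g))
})

test_that("declared graph shapes match executed tensor shapes", {
  g <- build_student(32, 6, seed = 1)
  m <- init_model(g)
  x <- array(0.5, dim = c(32, 32, 3, 2))
  fw <- cenkd:::forward_pass(m, x, train = FALSE)
  shapes <- graph_shapes(g)
  for (id in names(g$nodes)) {
    out <- fw$cache[[id]]$out
    d <- if (is.matrix(out)) c(1L, 1L, nrow(out)) else dim(out)[1:3]
    expect_identical(d, shapes[[id]],
                     info = paste("shape mismatch at node", id))
  }
})

test_that("model graphs survive YAML and JSON round trips", {
  g <- build_student(64, 6, seed = 3)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model_graph(g, path)
    g2 <- read_model_graph(path)
    expect_identical(names(g2$nodes), names(g$nodes))
    expect_identical(g2$output, g$output)
    expect_identical(g2$logits, g$logits)
    expect_identical(profile(g2)$total_flops, profile(g)$total_flops)
    expect_identical(count_params(g2), count_params(g))
    unlink(path)
  }
  expect_error(write_model_graph(g, tempfile(fileext = ".txt")),
               "unsupported")
})
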