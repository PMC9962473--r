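Package: leafcount
Title: Leaf Counting in Monocot Plants by Image Preprocessing, Skeletonization and Deep Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for counting leaves of monocot plants (sorghum, maize)
    from greenhouse-style RGB images. Extracts the plant by averaged-background
    differencing, Otsu binarization and largest-connected-component cropping;
    derives denoised skeleton-structure images by thinning, dilation and
    small-component removal; expands training sets with a twelve-member
    label-preserving geometric augmentation family; trains a convolutional
    count-regression model with a global-average-pooling single-unit head;
    evaluates predictions by RMSE, coefficient of determination and rounded
    accuracy; and explains trained models with background-colored
    sliding-window occlusion maps and Grad-CAM heatmaps with sigmoid emphasis.
    Includes a procedural generator of synthetic monocot plant images with
    known leaf counts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
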