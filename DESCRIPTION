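Package: voxelparcel
Title: Spatial Parcellation of Voxel-Level Gene Expression Atlases by
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering the genomic anatomy of brain structures
    from registered voxel-level gene expression atlases. Implements
    alternating-least-squares non-negative matrix factorization with
    negative clamping of a genes-by-voxels expression-energy matrix,
    argmax-weight clustering of voxels with back-registration to the 3D
    grid, signature-gene ranking and sparseness summaries of the basis
    vectors, a differential-enrichment screen between two voxel sets with
    standard-deviation flagging, and a replicate-correlation gene
    quality-control filter. A synthetic-atlas generator plants spatially
    contiguous expression domains with known signature genes so that every
    pipeline stage can be validated against ground truth without any atlas
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    grDevices,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
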