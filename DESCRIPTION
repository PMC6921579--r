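Package: bspim
Title: Biospeckle Light-Sheet Quantification of Nematode Bioactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the bioactivity of free-living nematodes from
    biospeckle selective plane illumination microscopy (BSPIM) scans.
    Frame bursts captured at successive stage steps are reduced to maps
    of dynamic-speckle activity by the generalized differences method,
    stacked into 3D activity volumes, background-subtracted and filtered,
    and segmented into biospeckle objects whose voxel counts, mean
    intensities, projected convex-hull circularities and integrated
    densities describe nematode size, motility and internal activity.
    Includes time-course normalization and paired/unpaired t-test
    screening summaries for chemical toxicity assays, and a synthetic
    scan simulator with trophic-group-specific worm motion and
    activity-coupled speckle decorrelation for fully reproducible
    testing without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
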