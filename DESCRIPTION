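Package: curvedslices
Title: Curved Slices in CT/MRI Volumes: Texturization and Isometric Flattening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts, texturizes and displays curved slices fitted to
    anatomical regions inside 3D medical volumes. Reads DICOM series and
    places every pixel in patient coordinates, generates synthetic phantom
    volumes with known analytic gray fields, paints parametric surfaces by
    trilinear interpolation or sub-box nearest-neighbor lookup, fits
    ellipsoids of revolution and least-squares Bezier centerlines, builds
    developable ruled surfaces along space curves, and unfolds them
    isometrically into the plane via the geodesic-curvature-preserving
    development, with a metric-distortion audit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    minpack.lm,
    pracma,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'curves.R'
    'AllClasses.R'
    'dicom-write.R'
    'dicom-read.R'
    'volume.R'
    'fields.R'
    'phantoms.R'
    'texturize.R'
    'ellipsoid.R'
    'ruled.R'
    'flatten.R'
    'serialize.R'
    'raster.R'
    'cli.R'
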