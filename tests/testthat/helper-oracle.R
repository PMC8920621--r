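# Independent marching-cubes oracle: scikit-image's classic (Lorensen)
# implementation, driven through one python subprocess.  Returns, for every
# corner sign pattern, the triangle count and sorted vertex set on a single
# cell, plus counts and vertices for the sphere fixture and counts for the
# torus fixture.
run_mc_oracle <- function() {
  script <- '
import json, sys
import numpy as np
from skimage import measure

corners = [(0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)]
out = {"cases": {}}
for ci in range(256):
    vol = np.zeros((2,2,2))
    for k in range(8):
        if (ci >> k) & 1:
            vol[corners[k]] = 1.0
    if ci in (0, 255):
        out["cases"][str(ci)] = {"nt": 0, "verts": []}
        continue
    v, f, n, _ = measure.marching_cubes(vol, 0.5, method="lorensen")
    verts = sorted(map(tuple, np.round(v, 9).tolist()))
    out["cases"][str(ci)] = {"nt": int(len(f)), "verts": verts}

x, y, z = np.mgrid[0:17, 0:17, 0:17].astype(float)
f = 4.7 - np.sqrt((x - 8.5)**2 + (y - 8.3)**2 + (z - 8.1)**2)
v, fa, n, _ = measure.marching_cubes(f, 0.0, method="lorensen")
out["sphere"] = {"nt": int(len(fa)), "nv": int(len(v)),
                 "verts": np.asarray(v, dtype=float).tolist()}

x, y, z = np.mgrid[0:41, 0:41, 0:17].astype(float)
X = -1.5 + x*0.075 - 0.0131
Y = -1.5 + y*0.075 - 0.0087
Z = -0.6 + z*0.075 + 0.0053
f = 0.4 - np.sqrt((np.sqrt(X**2 + Y**2) - 1.0)**2 + Z**2)
v, fa, n, _ = measure.marching_cubes(f, 0.0, method="lorensen")
out["torus"] = {"nt": int(len(fa)), "nv": int(len(v))}
json.dump(out, sys.stdout)
'
  json <- system2("python", c("-"), input = script, stdout = TRUE)
  jsonlite::fromJSON(paste(json, collapse = ""), simplifyVector = TRUE)
}

sort_rows <- function(m) {
  m <- matrix(as.numeric(m), ncol = 3L)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
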