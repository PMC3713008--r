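"""Convert a DICOM series directory into a 4D NIfTI + JSON sidecar.

Sorting key: (AcquisitionTime, InstanceNumber), falling back to
InstanceNumber alone when AcquisitionTime is absent. Frames sharing an
AcquisitionTime form one time point; a non-uniform slice count across time
points aborts the conversion.

Usage: python dicom_to_nifti.py <dicom_dir> <out.nii>
"""
import json
import os
import sys

import nibabel as nib
import numpy as np
import pydicom


def main(dicom_dir, out_nii):
    files = sorted(
        os.path.join(dicom_dir, f)
        for f in os.listdir(dicom_dir)
        if not f.startswith(".")
    )
    dsets = []
    for f in files:
        try:
            dsets.append(pydicom.dcmread(f))
        except Exception:
            continue
    if not dsets:
        raise SystemExit("no readable DICOM files in %s" % dicom_dir)

    have_time = all(getattr(d, "AcquisitionTime", None) for d in dsets)
    if have_time:
        dsets.sort(key=lambda d: (str(d.AcquisitionTime), int(d.InstanceNumber)))
        keys = [str(d.AcquisitionTime) for d in dsets]
    else:
        sys.stderr.write("warning: AcquisitionTime missing, sorting by InstanceNumber only\n")
        dsets.sort(key=lambda d: int(d.InstanceNumber))
        keys = None

    if keys is not None:
        times = sorted(set(keys), key=keys.index)
        groups = [[d for d, k in zip(dsets, keys) if k == t] for t in times]
        counts = {len(g) for g in groups}
        if len(counts) != 1:
            raise SystemExit("non-uniform slice count across time points: %s" % sorted(counts))
        n_slices = counts.pop()
    else:
        n_slices = 1
        groups = [[d] for d in dsets]

    vol = np.stack(
        [np.stack([d.pixel_array.astype(np.float64) for d in g], axis=-1) for g in groups],
        axis=-1,
    )  # (row, col, slice, time)

    d0 = dsets[0]
    te = float(getattr(d0, "EchoTime", 0) or 0)
    tr = float(getattr(d0, "RepetitionTime", 0) or 0)
    meta = {"Provenance": "dicom:%s" % dicom_dir}
    if te > 0:
        meta["EchoTime"] = te / 1000.0
    if tr > 0:
        meta["RepetitionTime"] = tr / 1000.0

    write_nifti(out_nii, vol, tr / 1000.0 if tr > 0 else 1.0)
    with open(os.path.splitext(out_nii)[0] + ".json", "w") as fh:
        json.dump(meta, fh)


def write_nifti(path, vol, tr_s):
    img = nib.Nifti1Image(vol.astype(np.float64), affine=np.eye(4))
    zooms = [1.0] * vol.ndim
    if vol.ndim >= 4:
        zooms[3] = tr_s
    img.header.set_zooms(zooms)
    nib.save(img, path)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
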