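# Generates a tiny synthetic DICOM series at test time with pydicom (the
# deliverable stays text-only). Returns the directory, or NULL if generation
# fails.
make_test_dicom_dir <- function(dir, n_time = 3L, n_slices = 2L, size = 8L,
                                uniform = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

out = r"%s"
n_time, n_slices, size = %d, %d, %d
uniform = %s
inst = 0
for t in range(n_time):
    slices = n_slices if (uniform or t == 0) else n_slices - 1
    for s in range(slices):
        inst += 1
        meta = FileMetaDataset()
        meta.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage
        meta.MediaStorageSOPInstanceUID = generate_uid()
        meta.TransferSyntaxUID = ExplicitVRLittleEndian
        ds = Dataset()
        ds.file_meta = meta
        ds.SOPClassUID = meta.MediaStorageSOPClassUID
        ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
        ds.Modality = "MR"
        ds.EchoTime = "47"
        ds.RepetitionTime = "1440"
        ds.AcquisitionTime = "1200%%02d.00" %% t
        ds.InstanceNumber = inst
        ds.SliceLocation = float(s * 5)
        ds.Rows = size
        ds.Columns = size
        ds.SamplesPerPixel = 1
        ds.PhotometricInterpretation = "MONOCHROME2"
        ds.BitsAllocated = 16
        ds.BitsStored = 16
        ds.HighBit = 15
        ds.PixelRepresentation = 0
        arr = np.full((size, size), 100 + 10 * t + s, dtype=np.uint16)
        ds.PixelData = arr.tobytes()
        ds.save_as("%%s/img_%%03d.dcm" %% (out, inst), enforce_file_format=True)
print("ok")
', dir, n_time, n_slices, size, if (uniform) "True" else "False"), script)
  res <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = TRUE))
  if (!any(grepl("^ok$", res))) return(NULL)
  dir
}
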