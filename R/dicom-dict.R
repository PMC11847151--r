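# Minimal DICOM data dictionary: the attributes needed for CT image series,
# RT Structure Sets, RT Plans and RT Dose grids. Tags are (group, element)
# integer pairs; VR is the DICOM value representation.

.dcm_dict_raw <- list(
  # file meta (group 0002, always explicit VR little endian)
  FileMetaInformationGroupLength = list(0x0002L, 0x0000L, "UL"),
  FileMetaInformationVersion     = list(0x0002L, 0x0001L, "OB"),
  MediaStorageSOPClassUID        = list(0x0002L, 0x0002L, "UI"),
  MediaStorageSOPInstanceUID     = list(0x0002L, 0x0003L, "UI"),
  TransferSyntaxUID              = list(0x0002L, 0x0010L, "UI"),
  ImplementationClassUID         = list(0x0002L, 0x0012L, "UI"),
  # general
  SpecificCharacterSet      = list(0x0008L, 0x0005L, "CS"),
  ImageType                 = list(0x0008L, 0x0008L, "CS"),
  SOPClassUID               = list(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID            = list(0x0008L, 0x0018L, "UI"),
  StudyDate                 = list(0x0008L, 0x0020L, "DA"),
  SeriesDate                = list(0x0008L, 0x0021L, "DA"),
  StudyTime                 = list(0x0008L, 0x0030L, "TM"),
  Modality                  = list(0x0008L, 0x0060L, "CS"),
  StudyDescription          = list(0x0008L, 0x1030L, "LO"),
  SeriesDescription         = list(0x0008L, 0x103EL, "LO"),
  ReferencedStudySequence   = list(0x0008L, 0x1110L, "SQ"),
  ReferencedSOPClassUID     = list(0x0008L, 0x1150L, "UI"),
  ReferencedSOPInstanceUID  = list(0x0008L, 0x1155L, "UI"),
  PatientName               = list(0x0010L, 0x0010L, "PN"),
  PatientID                 = list(0x0010L, 0x0020L, "LO"),
  SliceThickness            = list(0x0018L, 0x0050L, "DS"),
  StudyInstanceUID          = list(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID         = list(0x0020L, 0x000EL, "UI"),
  StudyID                   = list(0x0020L, 0x0010L, "SH"),
  SeriesNumber              = list(0x0020L, 0x0011L, "IS"),
  InstanceNumber            = list(0x0020L, 0x0013L, "IS"),
  ImagePositionPatient      = list(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient   = list(0x0020L, 0x0037L, "DS"),
  FrameOfReferenceUID       = list(0x0020L, 0x0052L, "UI"),
  SamplesPerPixel           = list(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation = list(0x0028L, 0x0004L, "CS"),
  NumberOfFrames            = list(0x0028L, 0x0008L, "IS"),
  Rows                      = list(0x0028L, 0x0010L, "US"),
  Columns                   = list(0x0028L, 0x0011L, "US"),
  PixelSpacing              = list(0x0028L, 0x0030L, "DS"),
  BitsAllocated             = list(0x0028L, 0x0100L, "US"),
  BitsStored                = list(0x0028L, 0x0101L, "US"),
  HighBit                   = list(0x0028L, 0x0102L, "US"),
  PixelRepresentation       = list(0x0028L, 0x0103L, "US"),
  RescaleIntercept          = list(0x0028L, 0x1052L, "DS"),
  RescaleSlope              = list(0x0028L, 0x1053L, "DS"),
  # RT dose
  DoseUnits                 = list(0x3004L, 0x0002L, "CS"),
  DoseType                  = list(0x3004L, 0x0004L, "CS"),
  DoseSummationType         = list(0x3004L, 0x000AL, "CS"),
  GridFrameOffsetVector     = list(0x3004L, 0x000CL, "DS"),
  DoseGridScaling           = list(0x3004L, 0x000EL, "DS"),
  # RT structure set
  StructureSetLabel         = list(0x3006L, 0x0002L, "SH"),
  StructureSetDate          = list(0x3006L, 0x0008L, "DA"),
  ReferencedFrameOfReferenceSequence = list(0x3006L, 0x0010L, "SQ"),
  RTReferencedStudySequence = list(0x3006L, 0x0012L, "SQ"),
  RTReferencedSeriesSequence = list(0x3006L, 0x0014L, "SQ"),
  ContourImageSequence      = list(0x3006L, 0x0016L, "SQ"),
  StructureSetROISequence   = list(0x3006L, 0x0020L, "SQ"),
  ROINumber                 = list(0x3006L, 0x0022L, "IS"),
  ReferencedFrameOfReferenceUID = list(0x3006L, 0x0024L, "UI"),
  ROIName                   = list(0x3006L, 0x0026L, "LO"),
  ROIGenerationAlgorithm    = list(0x3006L, 0x0036L, "CS"),
  ROIContourSequence        = list(0x3006L, 0x0039L, "SQ"),
  ContourSequence           = list(0x3006L, 0x0040L, "SQ"),
  ContourGeometricType      = list(0x3006L, 0x0042L, "CS"),
  NumberOfContourPoints     = list(0x3006L, 0x0046L, "IS"),
  ContourData               = list(0x3006L, 0x0050L, "DS"),
  ReferencedROINumber       = list(0x3006L, 0x0084L, "IS"),
  # RT plan
  RTPlanLabel               = list(0x300AL, 0x0002L, "SH"),
  RTPlanDate                = list(0x300AL, 0x0006L, "DA"),
  ReferencedRTPlanSequence  = list(0x300CL, 0x0002L, "SQ"),
  ReferencedStructureSetSequence = list(0x300CL, 0x0060L, "SQ"),
  PixelData                 = list(0x7FE0L, 0x0010L, "OW")
)

.dcm_tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

# name -> list(group, elem, vr, key)
.dcm_dict <- local({
  d <- lapply(.dcm_dict_raw, function(x) {
    list(group = x[[1]], elem = x[[2]], vr = x[[3]],
         key = .dcm_tag_key(x[[1]], x[[2]]))
  })
  d
})

# tag key -> VR, used when parsing implicit VR little endian
.dcm_vr_by_key <- local({
  keys <- vapply(.dcm_dict, `[[`, "", "key")
  vrs <- vapply(.dcm_dict, `[[`, "", "vr")
  stats::setNames(vrs, keys)
})

# SOP class UIDs
DCM_UID <- list(
  ExplicitVRLittleEndian = "1.2.840.10008.1.2.1",
  ImplicitVRLittleEndian = "1.2.840.10008.1.2",
  CTImageStorage        = "1.2.840.10008.5.1.4.1.1.2",
  MRImageStorage        = "1.2.840.10008.5.1.4.1.1.4",
  RTStructStorage       = "1.2.840.10008.5.1.4.1.1.481.3",
  RTPlanStorage         = "1.2.840.10008.5.1.4.1.1.481.5",
  RTDoseStorage         = "1.2.840.10008.5.1.4.1.1.481.2",
  StudyComponent        = "1.2.840.10008.3.1.2.3.2"
)

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "LO", "LT", "PN", "SH", "ST",
                     "TM", "UI", "UC", "UR")
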