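# Programmatic minimal mzML fixture (MS2 scan, 64-bit uncompressed arrays).

write_tiny_mzml <- function(path, mz, intensity, precursor_mz = 500.25,
                            charge = 2, rt = 63.2, ms_level = 2) {
  b64 <- function(x) {
    jsonlite::base64_enc(writeBin(x, raw(), size = 8, endian = "little"))
  }
  e1 <- b64(as.numeric(mz))
  e2 <- b64(as.numeric(intensity))
  xml <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
      '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="urn:ms"/></cvList>\n',
      '<fileDescription><fileContent>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '</fileContent></fileDescription>\n',
      '<softwareList count="1"><software id="sw" version="0">',
      '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
      '</software></softwareList>\n',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
      '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '</instrumentConfiguration></instrumentConfigurationList>\n',
      '<dataProcessingList count="1"><dataProcessing id="dp">',
      '<processingMethod order="1" softwareRef="sw">',
      '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '</processingMethod></dataProcessing></dataProcessingList>\n',
      '<run id="run" defaultInstrumentConfigurationRef="ic">\n',
      '<spectrumList count="1" defaultDataProcessingRef="dp">\n',
      '<spectrum index="0" id="scan=1" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
      'value="%g" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
      '</scan></scanList>\n',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%g"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>\n',
      '</selectedIon></selectedIonList>',
      '<activation><cvParam cvRef="MS" accession="MS:1000422" ',
      'name="beam-type collision-induced dissociation" value=""/></activation>',
      '</precursor></precursorList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum></spectrumList></run></mzML>'
    ),
    length(mz), ms_level, rt, precursor_mz, charge,
    nchar(e1), e1, nchar(e2), e2
  )
  writeLines(xml, path)
  invisible(path)
}
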