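id,age_years,sex,asa,mechanism,pupil_reactivity,pupil_size,gcs_motor,cpr,sbp,inr,hb,base_deficit,injuries,transferred_in,transferred_out_48h,outcome
p1,30,male,1,blunt,brisk,normal,6,no,125,1.05,14.2,2.0,3:chest;2:extremities_pelvis,FALSE,FALSE,survived
p2,82,female,3,blunt,fixed,bilateral_dilated,1,,,,,,5:head_neck;3:chest,FALSE,FALSE,died
p3,47,male,,penetrating,,,5,no,85,1.62,9.8,7.5,4:abdomen;3:abdomen,FALSE,FALSE,survived
p4,8,female,1,blunt,brisk,normal,6,no,110,,12.5,,2:head_neck;2:face,FALSE,FALSE,survived
p5,63,male,2,blunt,sluggish,anisocoria,4,yes,70,2.8,6.1,16.0,5:chest;5:chest;4:abdomen,FALSE,FALSE,died
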