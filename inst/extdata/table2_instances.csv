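subject_id,diagnosis,limb_id,mean,max,osc,nihss,mrc
S01,Lt internal capsule infarction,ULL,0.82,2.7,14.4,0,9
S01,Lt internal capsule infarction,URL,-3,-1.9,15.3,0,8
S01,Lt internal capsule infarction,LLL,-1.19,2.1,25.1,0,9
S01,Lt internal capsule infarction,LRL,11.81,17.4,30.8,1,8
S02,Lt MCA infarction,ULL,-9.33,-12,15.9,0,8
S02,Lt MCA infarction,URL,-6.47,-9.2,11.7,1,7
S02,Lt MCA infarction,LLL,18.7,10.7,43.5,0,8
S02,Lt MCA infarction,LRL,30.26,27.7,13.6,1,7
S03,Lt MCA infarction,ULL,0.86,0,7,0,9
S03,Lt MCA infarction,URL,4.06,1.4,13.8,0,9
S03,Lt MCA infarction,LLL,2.96,0,24.9,0,9
S03,Lt MCA infarction,LRL,9.91,-1.6,61.5,1,7
S04,Lt MCA infarction,ULL,3.16,4.2,14.5,0,9
S04,Lt MCA infarction,URL,2.3,3.2,19.1,0,9
S04,Lt MCA infarction,LLL,0.26,1.6,12.9,0,9
S04,Lt MCA infarction,LRL,4.26,8.4,21.7,0,8
S05,Lt MCA infarction,ULL,1.92,3.6,14.6,0,9
S05,Lt MCA infarction,URL,3.14,4.2,14.5,0,9
S05,Lt MCA infarction,LLL,1.84,5.7,39.5,0,9
S05,Lt MCA infarction,LRL,0.75,2.9,19.6,0,9
S06,Lt pontine infarction,ULL,-0.67,0.6,19.5,1,7
S06,Lt pontine infarction,URL,-1.37,1.3,12.9,0,8
S06,Lt pontine infarction,LLL,-11.93,-10.3,16.7,1,7
S06,Lt pontine infarction,LRL,-4.93,-2.1,17.3,1,8
S07,Lt thalamic infarction,ULL,2.05,3.5,22.8,0,9
S07,Lt thalamic infarction,URL,8.91,11.4,12.5,1,7
S07,Lt thalamic infarction,LLL,4.77,8.8,31.3,0,9
S07,Lt thalamic infarction,LRL,1.98,6.8,37.7,1,8
S08,Pontine ICH,ULL,-1.57,1.5,39.1,1,7
S08,Pontine ICH,URL,0.81,2,18.5,0,9
S08,Pontine ICH,LLL,-3,1.2,40,1,8
S08,Pontine ICH,LRL,3.18,5.3,16.5,0,9
S09,Rt MCA infarction,ULL,-9.96,-7.5,17.9,1,7
S09,Rt MCA infarction,URL,-1.93,-0.6,19,0,9
S09,Rt MCA infarction,LLL,-2.71,0.4,18.5,1,7
S09,Rt MCA infarction,LRL,-1.99,-0.3,17.2,0,9
S10,Lt internal capsule infarction,ULL,-6,-7.9,14,0,9
S10,Lt internal capsule infarction,URL,-0.8,-2,11.6,0,9
S10,Lt internal capsule infarction,LLL,1.8,0.8,18.6,0,8
S10,Lt internal capsule infarction,LRL,11,6.5,38.5,0,9
S11,Myelitis (no weakness),ULL,1.3,2.9,18.6,0,9
S11,Myelitis (no weakness),URL,-0.56,0.1,11.7,0,9
S11,Myelitis (no weakness),LLL,-1.23,1.2,24.1,0,9
S11,Myelitis (no weakness),LRL,-1.14,0.7,24,0,9
S12,Rt MCA infarction,ULL,-4.97,-6.4,19.2,0,9
S12,Rt MCA infarction,URL,0.7,0,13.1,0,9
S12,Rt MCA infarction,LLL,13.9,7,49.3,1,7
S12,Rt MCA infarction,LRL,6.31,2.3,34.3,0,9
S13,Myasthenia gravis,ULL,-0.64,1.3,19.2,0,9
S13,Myasthenia gravis,URL,1.1,2.7,14.4,0,9
S13,Myasthenia gravis,LLL,-1.97,0,18.5,0,9
S13,Myasthenia gravis,LRL,-0.64,2.7,22.6,0,9
S14,Lt pontine infarction,ULL,15.5,5.4,41.1,0,9
S14,Lt pontine infarction,URL,23.5,12,54,1,7
S14,Lt pontine infarction,LLL,6.3,2.2,26.1,0,9
S14,Lt pontine infarction,LRL,5.3,0.6,46.2,1,7
S15,Pontine hemorrhage,ULL,-0.83,1.1,19,1,8
S15,Pontine hemorrhage,URL,-2.72,1.3,26.6,1,8
S15,Pontine hemorrhage,LLL,1.69,3.3,13.6,1,8
S15,Pontine hemorrhage,LRL,-7.52,-0.8,54.5,1,7
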