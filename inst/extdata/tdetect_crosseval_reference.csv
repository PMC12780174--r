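architecture,trainingData,testData,domain,metric,mean,sd
unet,experimental_noisy,experimental,sinogram,ssim,0.8126,0.0194
unet,experimental_noisy,simulated,sinogram,ssim,0.8167,0.0199
unet,experimental_noisy,experimental,sinogram,psnr,18.4966,0.6278
unet,experimental_noisy,simulated,sinogram,psnr,19.3181,0.5575
unet,simulated_noisy,experimental,sinogram,ssim,0.8273,0.0240
unet,simulated_noisy,simulated,sinogram,ssim,0.8795,0.0206
unet,simulated_noisy,experimental,sinogram,psnr,33.4602,0.9533
unet,simulated_noisy,simulated,sinogram,psnr,36.6016,0.5616
msdnet,experimental_noisy,experimental,sinogram,ssim,0.8613,0.0211
msdnet,experimental_noisy,simulated,sinogram,ssim,0.8239,0.0216
msdnet,experimental_noisy,experimental,sinogram,psnr,36.2182,0.7214
msdnet,experimental_noisy,simulated,sinogram,psnr,20.4747,0.6793
msdnet,simulated_noisy,experimental,sinogram,ssim,0.7512,0.0226
msdnet,simulated_noisy,simulated,sinogram,ssim,0.8835,0.0198
msdnet,simulated_noisy,experimental,sinogram,psnr,16.3208,1.3965
msdnet,simulated_noisy,simulated,sinogram,psnr,38.0265,0.7412
unet,experimental_noisy,experimental,reconstruction_of_output,ssim,0.6134,0.0732
unet,experimental_noisy,simulated,reconstruction_of_output,ssim,0.6273,0.0717
unet,experimental_noisy,experimental,reconstruction_of_output,psnr,26.7127,1.9780
unet,experimental_noisy,simulated,reconstruction_of_output,psnr,27.5290,1.9405
unet,simulated_noisy,experimental,reconstruction_of_output,ssim,0.5504,0.0677
unet,simulated_noisy,simulated,reconstruction_of_output,ssim,0.6351,0.0713
unet,simulated_noisy,experimental,reconstruction_of_output,psnr,28.3307,2.0810
unet,simulated_noisy,simulated,reconstruction_of_output,psnr,32.5568,2.0169
msdnet,experimental_noisy,experimental,reconstruction_of_output,ssim,0.5984,0.0741
msdnet,experimental_noisy,simulated,reconstruction_of_output,ssim,0.6152,0.0723
msdnet,experimental_noisy,experimental,reconstruction_of_output,psnr,30.9185,1.9707
msdnet,experimental_noisy,simulated,reconstruction_of_output,psnr,28.3031,1.9314
msdnet,simulated_noisy,experimental,reconstruction_of_output,ssim,0.3854,0.0469
msdnet,simulated_noisy,simulated,reconstruction_of_output,ssim,0.6372,0.0469
msdnet,simulated_noisy,experimental,reconstruction_of_output,psnr,11.6366,2.3636
msdnet,simulated_noisy,simulated,reconstruction_of_output,psnr,32.6552,2.0173
unet,experimental_noisy,experimental,reconstruction_direct,ssim,0.8161,0.0592
unet,experimental_noisy,simulated,reconstruction_direct,ssim,0.7466,0.0681
unet,experimental_noisy,experimental,reconstruction_direct,psnr,29.8398,2.1834
unet,experimental_noisy,simulated,reconstruction_direct,psnr,28.0435,2.0848
unet,simulated_noisy,experimental,reconstruction_direct,ssim,0.5957,0.0844
unet,simulated_noisy,simulated,reconstruction_direct,ssim,0.6693,0.0820
unet,simulated_noisy,experimental,reconstruction_direct,psnr,26.8841,3.4800
unet,simulated_noisy,simulated,reconstruction_direct,psnr,28.8134,3.9418
msdnet,experimental_noisy,experimental,reconstruction_direct,ssim,0.7829,0.0749
msdnet,experimental_noisy,simulated,reconstruction_direct,ssim,0.7892,0.0731
msdnet,experimental_noisy,experimental,reconstruction_direct,psnr,32.0684,1.9309
msdnet,experimental_noisy,simulated,reconstruction_direct,psnr,32.0704,1.9580
msdnet,simulated_noisy,experimental,reconstruction_direct,ssim,0.7615,0.0702
msdnet,simulated_noisy,simulated,reconstruction_direct,ssim,0.8204,0.0567
msdnet,simulated_noisy,experimental,reconstruction_direct,psnr,30.6211,2.0626
msdnet,simulated_noisy,simulated,reconstruction_direct,psnr,33.1053,2.0120
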